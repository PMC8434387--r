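# Leave-one-subject-out training protocol, macro-averaged evaluation metrics,
# fold aggregation, and the ablation/experiment runner.

#' Training configuration
#'
#' Defaults follow the study protocol: Adam with initial learning rate 1e-4
#' decayed by a factor of 0.1 every 20 epochs, L2 regularization with weight
#' decay 0.1 on convolution and fully connected weights, 100 epochs, batch
#' size 256, and best-validation-accuracy model selection.
#'
#' @param lr Initial learning rate.
#' @param lr_decay_factor,lr_decay_every Stepped schedule:
#'   `lr * lr_decay_factor^floor(epoch / lr_decay_every)`.
#' @param weight_decay L2 coefficient `lambda`; the penalty gradient
#'   `lambda * w` is added to convolution and fully connected weight
#'   gradients.
#' @param decay_bn_and_bias If `TRUE`, also decay biases and batch-norm
#'   affine parameters (strict all-parameters mode).
#' @param epochs,batch_size Optimization budget.  The last incomplete batch
#'   is kept; shuffling is reseeded per epoch from `seed`.
#' @param loss Loss name understood by [make_loss()].
#' @param beta,gamma Loss hyperparameters (see [cb_focal_loss()]).
#' @param norm_scope `"fold"` fits standardization on the fold's training
#'   subjects only (default, avoids leakage); `"global"` fits on all provided
#'   segments, the alternative reading of the preprocessing description.
#' @param seed Seed controlling initialization-independent randomness of a
#'   fold run (shuffling).
#' @return Object of class `cminet_train_config`.
#' @export
train_config <- function(lr = 1e-4, lr_decay_factor = 0.1, lr_decay_every = 20L,
                         weight_decay = 0.1, decay_bn_and_bias = FALSE,
                         epochs = 100L, batch_size = 256L,
                         loss = "cb_focal", beta = 0.9999, gamma = NULL,
                         norm_scope = c("fold", "global"), seed = 1L) {
  norm_scope <- match.arg(norm_scope)
  stopifnot(lr > 0, lr_decay_factor > 0, lr_decay_every >= 1L,
            weight_decay >= 0, epochs >= 1L, batch_size >= 1L)
  structure(list(lr = lr, lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 weight_decay = weight_decay,
                 decay_bn_and_bias = isTRUE(decay_bn_and_bias),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 loss = loss, beta = beta, gamma = gamma,
                 norm_scope = norm_scope, seed = as.integer(seed)),
            class = "cminet_train_config")
}

#' Learning rate at a given epoch
#'
#' @param config A [train_config()].
#' @param epoch Zero-based epoch index.
#' @return The stepped learning rate
#'   `lr * factor^floor(epoch / every)`.
#' @export
lr_at_epoch <- function(config, epoch) {
  stopifnot(all(epoch >= 0))
  config$lr * config$lr_decay_factor^(floor(epoch / config$lr_decay_every))
}

#' Leave-one-subject-out folds
#'
#' One fold per subject as the test set; the validation subject is the
#' cyclically next subject and the remaining subjects train, rotating in a
#' circular manner.
#'
#' @param subject_ids Vector of at least 3 distinct subject identifiers.
#' @return List of folds, each `list(train, val, test)`.
#' @export
loocv_splits <- function(subject_ids) {
  ids <- as.character(unique(subject_ids))
  n <- length(ids)
  if (n < 3L) stop("leave-one-subject-out needs at least 3 distinct subjects")
  lapply(seq_len(n), function(i) {
    test <- ids[i]
    val <- ids[(i %% n) + 1L]
    list(train = setdiff(ids, c(test, val)), val = val, test = test)
  })
}

#' Confusion matrix from truth and prediction indices
#'
#' @param truth,pred Integer class indices in `1..n_classes`.
#' @param n_classes Number of classes.
#' @param class_names Optional dimnames.
#' @return `n_classes x n_classes` integer matrix, rows = ground truth,
#'   columns = prediction.
#' @export
confusion_matrix <- function(truth, pred, n_classes = 6L,
                             class_names = activity_classes()) {
  stopifnot(length(truth) == length(pred),
            all(truth >= 1L & truth <= n_classes),
            all(pred >= 1L & pred <= n_classes))
  class_names <- class_names[seq_len(n_classes)]
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(truth = class_names, pred = class_names))
  tab <- table(factor(truth, levels = seq_len(n_classes)),
               factor(pred, levels = seq_len(n_classes)))
  cm[] <- as.integer(tab)
  cm
}

#' Macro-averaged classification metrics
#'
#' Per class `c` (one-vs-rest): `TP = cm[c,c]`, `FP` the rest of column `c`,
#' `FN` the rest of row `c`; precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' F1 `2TP/(2TP+FP+FN)`.  Overall precision/recall/F1 are unweighted
#' (macro) means over classes and accuracy is `trace/total`; every value is
#' multiplied by 100.  A class never predicted gets precision 0 with a
#' warning (and likewise recall for a class never observed).
#'
#' @param cm Square confusion matrix of counts, rows = ground truth.
#' @return List with `precision`, `recall`, `f1`, `accuracy` (scalars, x100)
#'   and `per_class` (data frame of per-class values, x100).
#' @export
compute_metrics <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  total <- sum(cm)
  if (total == 0) stop("confusion matrix is empty")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  div0 <- function(num, den, what) {
    bad <- den == 0
    if (any(bad))
      warning("class(es) with no ", what, " support get 0: ",
              paste(rownames(cm)[bad] %||% which(bad), collapse = ", "))
    ifelse(bad, 0, num / den)
  }
  precision <- div0(tp, tp + fp, "prediction")
  recall <- div0(tp, tp + fn, "ground-truth")
  f1 <- div0(2 * tp, 2 * tp + fp + fn, "either-side")
  per_class <- data.frame(class = rownames(cm) %||% seq_len(nrow(cm)),
                          n = rowSums(cm),
                          precision = 100 * precision,
                          recall = 100 * recall,
                          f1 = 100 * f1,
                          row.names = NULL)
  list(precision = 100 * mean(precision),
       recall = 100 * mean(recall),
       f1 = 100 * mean(f1),
       accuracy = 100 * sum(tp) / total,
       per_class = per_class)
}

#' Pool fold results
#'
#' Element-wise sum of the folds' confusion matrices, the row-normalized
#' recall matrix and column-normalized precision matrix (each x100), and the
#' pooled metrics recomputed from the pooled counts.
#'
#' @param fold_results List of results from [train_fold()] (or any objects
#'   with a `$confusion` matrix).
#' @return List with `confusion`, `recall_matrix`, `precision_matrix`, and
#'   `metrics`.
#' @export
aggregate_folds <- function(fold_results) {
  stopifnot(length(fold_results) >= 1L)
  cms <- lapply(fold_results, function(f) as.matrix(f$confusion))
  dims <- vapply(cms, nrow, 0L)
  if (length(unique(dims)) != 1L) stop("folds have mismatched class sets")
  pooled <- Reduce(`+`, cms)
  rn <- pooled / ifelse(rowSums(pooled) == 0, 1, rowSums(pooled)) * 100
  cn <- t(t(pooled) / ifelse(colSums(pooled) == 0, 1, colSums(pooled))) * 100
  list(confusion = pooled,
       recall_matrix = rn,
       precision_matrix = cn,
       metrics = compute_metrics(pooled))
}

# ---- batching --------------------------------------------------------------

# Stack segments into B x 3 x 200 arrays plus label / subject vectors,
# applying standardization if stats are given.
segments_to_arrays <- function(segments, stats = NULL) {
  if (!is.null(stats)) segments <- apply_normalization(segments, stats)
  B <- length(segments)
  accel <- array(0, c(B, 3L, 200L))
  gyro <- array(0, c(B, 3L, 200L))
  for (i in seq_len(B)) {
    accel[i, , ] <- segments[[i]]$accel
    gyro[i, , ] <- segments[[i]]$gyro
  }
  list(accel = accel, gyro = gyro,
       labels = encode_labels(vapply(segments, function(s) s$label, "")),
       subjects = vapply(segments, function(s) s$subject_id, ""))
}

# Predicted class indices for a stacked batch; argmax with ties broken by the
# lowest class index.
predict_classes <- function(model, arrays, batch_size = 512L) {
  B <- dim(arrays$accel)[1L]
  out <- integer(B)
  for (start in seq(1L, B, by = batch_size)) {
    ix <- start:min(start + batch_size - 1L, B)
    lg <- model_forward(model,
                        arrays$accel[ix, , , drop = FALSE],
                        arrays$gyro[ix, , , drop = FALSE])
    out[ix] <- max.col(lg, ties.method = "first")
  }
  out
}

# ---- Adam over the nested parameter list -----------------------------------

param_tree_map <- function(f, ...) {
  trees <- list(...)
  rec <- function(...) {
    xs <- list(...)
    if (is.list(xs[[1L]])) {
      out <- vector("list", length(xs[[1L]]))
      names(out) <- names(xs[[1L]])
      for (i in seq_along(out))
        out[[i]] <- do.call(rec, lapply(xs, `[[`, i))
      out
    } else {
      do.call(f, xs)
    }
  }
  do.call(rec, trees)
}

zeros_like_tree <- function(tree) param_tree_map(function(x) x * 0, tree)

adam_step <- function(params, grads, opt, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  opt$m <- param_tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                          opt$m, grads)
  opt$v <- param_tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                          opt$v, grads)
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  params <- param_tree_map(function(p, m, v)
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
    params, opt$m, opt$v)
  list(params = params, opt = opt)
}

# Add the L2 penalty gradient lambda * w.  By default only convolution and
# fully connected *weights* decay (names K1, K3, Kj, Ka, Kg, W); biases and
# batch-norm affine parameters are excluded.
add_weight_decay <- function(grads, params, lambda, all_params = FALSE) {
  if (lambda == 0) return(grads)
  decay_names <- c("K1", "K3", "Kj", "Ka", "Kg", "W")
  rec <- function(g, p) {
    if (is.list(g)) {
      for (nm in names(g)) {
        if (is.list(g[[nm]]) || nm %in% decay_names || all_params)
          g[[nm]] <- rec(g[[nm]], p[[nm]])
      }
      g
    } else {
      g + lambda * p
    }
  }
  rec(grads, params)
}

l2_penalty <- function(params, lambda, all_params = FALSE) {
  if (lambda == 0) return(0)
  decay_names <- c("K1", "K3", "Kj", "Ka", "Kg", "W")
  acc <- 0
  rec <- function(p) {
    if (is.list(p)) {
      for (nm in names(p))
        if (is.list(p[[nm]]) || nm %in% decay_names || all_params)
          rec(p[[nm]])
    } else {
      acc <<- acc + sum(p^2)
    }
    invisible(NULL)
  }
  rec(params)
  lambda / 2 * acc
}

# ---- fold training ---------------------------------------------------------

#' Train and evaluate one leave-one-subject-out fold
#'
#' Fits standardization on the fold's training subjects (unless
#' `norm_scope = "global"`), trains with Adam on
#' `loss + lambda/2 * ||w||^2` under the stepped learning-rate schedule,
#' computes validation accuracy after every epoch, keeps the parameters of
#' the highest-validation-accuracy epoch (earliest epoch on ties), and
#' evaluates that checkpoint on the held-out test subject.  Fully
#' reproducible given the model and training seeds.
#'
#' @param segments List of [sensor_segment()] covering all fold subjects.
#' @param fold One element of [loocv_splits()].
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param return_model Also return the selected model (default `FALSE`).
#' @param verbose Print per-epoch progress.
#' @return Object of class `cminet_fold_result`: `test_subject`,
#'   `best_epoch` (zero-based), `confusion`, `metrics`, `history` (per-epoch
#'   data frame), `norm_stats`, `train_subjects`, `class_counts`, and
#'   optionally `model`.
#' @export
train_fold <- function(segments, fold, model_cfg, train_cfg,
                       return_model = FALSE, verbose = FALSE) {
  stopifnot(inherits(model_cfg, "cminet_config"),
            inherits(train_cfg, "cminet_train_config"))
  subj <- vapply(segments, function(s) s$subject_id, "")
  for (part in c("train", "val", "test")) {
    if (!all(fold[[part]] %in% subj) || length(fold[[part]]) == 0L)
      stop("fold ", part, " subject(s) missing from the provided segments")
  }
  tr_segs <- segments[subj %in% fold$train]
  va_segs <- segments[subj %in% fold$val]
  te_segs <- segments[subj %in% fold$test]

  stats <- if (train_cfg$norm_scope == "global") fit_normalization(segments)
  else fit_normalization(tr_segs)
  tr <- segments_to_arrays(tr_segs, stats)
  va <- segments_to_arrays(va_segs, stats)
  te <- segments_to_arrays(te_segs, stats)

  counts <- class_distribution(tr_segs)$counts
  loss_counts <- pmax(counts, 1L) # absent classes never occur in batches
  loss_fn <- make_loss(train_cfg$loss, counts = loss_counts,
                       beta = train_cfg$beta, gamma = train_cfg$gamma)

  model <- build_model(model_cfg)
  opt <- list(t = 0L, m = zeros_like_tree(model$params),
              v = zeros_like_tree(model$params))
  B <- length(tr_segs)
  best <- list(acc = -Inf, epoch = NA_integer_, params = NULL, state = NULL)
  history <- vector("list", train_cfg$epochs)

  for (epoch in seq_len(train_cfg$epochs) - 1L) {
    lr <- lr_at_epoch(train_cfg, epoch)
    perm <- with_local_seed(train_cfg$seed + epoch, sample.int(B))
    epoch_loss <- 0
    nb <- 0L
    for (start in seq(1L, B, by = train_cfg$batch_size)) {
      ix <- perm[start:min(start + train_cfg$batch_size - 1L, B)]
      Xa <- batch_to_internal(tr$accel[ix, , , drop = FALSE])
      Xg <- batch_to_internal(tr$gyro[ix, , , drop = FALSE])
      fwd <- model_forward_internal(model, Xa, Xg, training = TRUE,
                                    keep_cache = TRUE)
      model$state <- fwd$state
      lo <- loss_fn(fwd$logits, tr$labels[ix], gradient = TRUE)
      if (!is.finite(lo$value))
        stop("training diverged: non-finite loss at epoch ", epoch,
             " (lr ", lr, ")")
      grads <- model_backward_internal(model, fwd, lo$gradient)
      grads <- add_weight_decay(grads, model$params, train_cfg$weight_decay,
                                train_cfg$decay_bn_and_bias)
      stepres <- adam_step(model$params, grads, opt, lr)
      model$params <- stepres$params
      opt <- stepres$opt
      epoch_loss <- epoch_loss + lo$value
      nb <- nb + 1L
    }
    val_pred <- predict_classes(model, va)
    val_acc <- mean(val_pred == va$labels)
    history[[epoch + 1L]] <- data.frame(epoch = epoch, lr = lr,
                                        train_loss = epoch_loss / nb,
                                        val_accuracy = 100 * val_acc)
    if (val_acc > best$acc) { # strict: earliest epoch wins ties
      best <- list(acc = val_acc, epoch = epoch, params = model$params,
                   state = model$state)
    }
    if (verbose)
      message(sprintf("epoch %3d  lr %.2g  loss %.4f  val acc %.2f%%",
                      epoch, lr, epoch_loss / nb, 100 * val_acc))
  }

  model$params <- best$params
  model$state <- best$state
  te_pred <- predict_classes(model, te)
  cm <- confusion_matrix(te$labels, te_pred, model_cfg$n_classes,
                         activity_classes()[seq_len(model_cfg$n_classes)])
  metrics <- suppressWarnings(compute_metrics(cm))
  out <- structure(list(test_subject = fold$test,
                        best_epoch = best$epoch,
                        best_val_accuracy = 100 * best$acc,
                        confusion = cm,
                        metrics = metrics,
                        history = do.call(rbind, history),
                        norm_stats = stats,
                        train_subjects = fold$train,
                        class_counts = counts),
                   class = "cminet_fold_result")
  if (return_model) out$model <- model
  out
}

#' @export
print.cminet_fold_result <- function(x, ...) {
  cat(sprintf(paste0("<cminet_fold_result> test subject %s, best epoch %d ",
                     "(val acc %.2f)\n  precision %.2f  recall %.2f  ",
                     "f1 %.2f  accuracy %.2f\n"),
              x$test_subject, x$best_epoch, x$best_val_accuracy,
              x$metrics$precision, x$metrics$recall, x$metrics$f1,
              x$metrics$accuracy))
  invisible(x)
}

# ---- experiment runner -----------------------------------------------------

# Tiny rolling hash of a serialized object, for run logs (exact in double
# arithmetic: values stay far below 2^53).
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run a (variant x loss x fold) experiment grid
#'
#' Executes every combination of model variant and loss over all
#' leave-one-subject-out folds, pooling fold confusion matrices per cell into
#' a summary table shaped like the study's ablation tables (columns
#' Precision/Recall/F1/Accuracy, x100).  Per-cell failures are recorded and
#' the run continues.  When `out_dir` is given, per-cell results are saved
#' and existing cells are skipped, making the run resumable.
#'
#' @param segments Dataset as a list of [sensor_segment()].
#' @param variants Named list of [model_config()] objects.
#' @param losses Named list, each `list(loss =, beta =, gamma =)` (missing
#'   hyperparameters take [train_config()] defaults).
#' @param train_cfg Base [train_config()]; its loss fields are overridden per
#'   cell.
#' @param folds Folds from [loocv_splits()]; default: all subjects present.
#' @param out_dir Optional directory for per-cell results and the run log.
#' @param verbose Print progress.
#' @return Object of class `cminet_experiment`: `summary` (data frame),
#'   `cells` (per-cell fold results and pooled matrices), `errors`,
#'   `config_hash`.
#' @export
run_experiment <- function(segments, variants, losses, train_cfg,
                           folds = NULL, out_dir = NULL, verbose = FALSE) {
  stopifnot(length(variants) >= 1L, length(losses) >= 1L)
  if (is.null(names(variants)) || is.null(names(losses)))
    stop("variants and losses must be named lists")
  if (is.null(folds))
    folds <- loocv_splits(vapply(segments, function(s) s$subject_id, ""))
  hash <- config_hash(list(variants = variants, losses = losses,
                           train = train_cfg, n = length(segments)))
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  cells <- list()
  errors <- list()
  rows <- list()
  for (vn in names(variants)) {
    for (ln in names(losses)) {
      cell_id <- paste(vn, ln, sep = ".")
      cell_file <- if (!is.null(out_dir))
        file.path(out_dir, paste0("cell-", cell_id, "-", hash, ".rds"))
      if (!is.null(out_dir) && file.exists(cell_file)) {
        fold_results <- readRDS(cell_file)
      } else {
        tc <- train_cfg
        ls <- losses[[ln]]
        tc$loss <- ls$loss %||% ln
        if (!is.null(ls$beta)) tc$beta <- ls$beta
        if (!is.null(ls$gamma)) tc$gamma <- ls$gamma
        fold_results <- list()
        for (fi in seq_along(folds)) {
          res <- tryCatch(
            train_fold(segments, folds[[fi]], variants[[vn]], tc),
            error = function(e) e)
          if (inherits(res, "error")) {
            errors[[paste(cell_id, folds[[fi]]$test, sep = ".")]] <-
              conditionMessage(res)
            if (verbose) message("cell ", cell_id, " fold ",
                                 folds[[fi]]$test, " FAILED: ",
                                 conditionMessage(res))
          } else {
            fold_results[[length(fold_results) + 1L]] <- res
            if (verbose) message("cell ", cell_id, " fold ",
                                 folds[[fi]]$test, " acc ",
                                 round(res$metrics$accuracy, 2))
          }
        }
        if (!is.null(out_dir)) saveRDS(fold_results, cell_file)
      }
      if (length(fold_results)) {
        agg <- aggregate_folds(fold_results)
        cells[[cell_id]] <- list(folds = fold_results, aggregate = agg)
        m <- agg$metrics
        rows[[cell_id]] <- data.frame(
          variant = vn, loss = ln, n_folds = length(fold_results),
          precision = m$precision, recall = m$recall, f1 = m$f1,
          accuracy = m$accuracy)
      }
    }
  }
  summary <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else data.frame()
  out <- structure(list(summary = summary, cells = cells, errors = errors,
                        config_hash = hash),
                   class = "cminet_experiment")
  if (!is.null(out_dir)) {
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    writeLines(c(paste("config hash:", hash),
                 paste("cells:", length(cells)),
                 paste("errors:", length(errors))),
               file.path(out_dir, "run-log.txt"))
  }
  out
}

#' @export
print.cminet_experiment <- function(x, ...) {
  cat("<cminet_experiment> hash", x$config_hash, "\n")
  print(x$summary, digits = 4)
  if (length(x$errors)) cat(length(x$errors), "cell failure(s)\n")
  invisible(x)
}

#' Build the standard ablation variants
#'
#' The attention-free network (`variant0`), the module after each of the
#' three max-pooling layers (`variant1..3`), and the full model with the
#' module after the last convolution block.
#'
#' @param base A [model_config()] whose `cmim_position` is overridden.
#' @return Named list of five [model_config()] objects.
#' @export
ablation_variants <- function(base = model_config()) {
  pos <- c(variant0 = "none", variant1 = "after_pool1",
           variant2 = "after_pool2", variant3 = "after_pool3",
           cmi_net = "after_block4")
  lapply(pos, function(p) {
    cfg <- base
    cfg$cmim_position <- p
    cfg
  })
}
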
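# The dual-branch network: two modality trunks of residual-like convolution
# blocks with time-only max pooling, an optional cross-modality interaction
# attention module (CMIM), global average pooling, one fully connected layer
# per branch, concatenation, and a joint fully connected classification head.

cmim_positions <- function() {
  c("none", "after_pool1", "after_pool2", "after_pool3", "after_block4")
}

#' Network configuration
#'
#' @param widths Channel width of each of the four convolution blocks per
#'   trunk.  The defaults double with depth as usual for this family of
#'   architectures.
#' @param cmim_position Where the cross-modality interaction module sits:
#'   `"none"` (the attention-free ablation variant), after the 1st/2nd/3rd
#'   max-pooling layer, or `"after_block4"` (the default: attention applied
#'   to the deepest features, just before global average pooling, where the
#'   full model performs best).
#' @param cmim_hidden Channel count of the joint representation inside the
#'   attention module.
#' @param fc_width Width of the per-branch fully connected layer; the joint
#'   head maps `2 * fc_width` to `n_classes`.
#' @param n_classes Number of activity classes (6).
#' @param seed Seed for the weight initialization, part of the configuration
#'   so builds are reproducible.
#' @return Object of class `cminet_config`.
#' @export
model_config <- function(widths = c(16L, 32L, 64L, 128L),
                         cmim_position = "after_block4",
                         cmim_hidden = 16L,
                         fc_width = 64L,
                         n_classes = 6L,
                         seed = 1L) {
  cmim_position <- match.arg(cmim_position, cmim_positions())
  stopifnot(length(widths) == 4L, all(widths >= 1L),
            cmim_hidden >= 1L, fc_width >= 1L, n_classes >= 2L)
  structure(list(widths = as.integer(widths),
                 cmim_position = cmim_position,
                 cmim_hidden = as.integer(cmim_hidden),
                 fc_width = as.integer(fc_width),
                 n_classes = as.integer(n_classes),
                 seed = as.integer(seed)),
            class = "cminet_config")
}

he_conv3 <- function(cout, cin) {
  array(stats::rnorm(cout * cin * 3, 0, sqrt(2 / (cin * 3))), c(cout, cin, 3L))
}
he_conv1 <- function(cout, cin) {
  matrix(stats::rnorm(cout * cin, 0, sqrt(2 / cin)), cout, cin)
}
he_fc <- function(cout, cin) {
  matrix(stats::rnorm(cout * cin, 0, sqrt(2 / cin)), cout, cin)
}

init_block <- function(cin, cout) {
  list(K1 = he_conv1(cout, cin), b1 = numeric(cout),
       g1 = rep(1, cout), be1 = numeric(cout),
       K3 = he_conv3(cout, cin), b3 = numeric(cout),
       g3 = rep(1, cout), be3 = numeric(cout))
}

init_bn_state <- function(c) list(mean = numeric(c), var = rep(1, c))

init_trunk <- function(widths) {
  cin <- c(1L, widths[-4L])
  lapply(1:4, function(i) init_block(cin[i], widths[i]))
}

#' Build the classifier
#'
#' Per trunk: block1 - pool - block2 - pool - block3 - pool - block4, with the
#' interaction module inserted at the configured site, then global average
#' pooling and one fully connected layer; the two branch vectors are
#' concatenated and a joint fully connected layer emits the class logits.
#' Weight initialization is a seeded fan-in scheme; trunk and head weights are
#' drawn before the attention module's, so models differing only in
#' `cmim_position` share identical trunk weights under the same seed.
#'
#' @param config A [model_config()] object.
#' @return Object of class `cminet_model` holding `config`, `params`
#'   (weights) and `state` (batch-normalization running statistics).
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "cminet_config"))
  w <- config$widths
  with_local_seed(config$seed, {
    params <- list(
      accel = init_trunk(w),
      gyro = init_trunk(w),
      fc_accel = list(W = he_fc(config$fc_width, w[4L]),
                      b = numeric(config$fc_width)),
      fc_gyro = list(W = he_fc(config$fc_width, w[4L]),
                     b = numeric(config$fc_width)),
      joint = list(W = he_fc(config$n_classes, 2L * config$fc_width),
                   b = numeric(config$n_classes))
    )
    if (config$cmim_position != "none") {
      cp <- config$cmim_hidden
      params$cmim <- list(
        Kj = he_conv3(cp, 2L), bj = numeric(cp),
        gj = rep(1, cp), bej = numeric(cp),
        Ka = he_conv3(1L, cp), ba = numeric(1L),
        ga = rep(1, 1L), bea = numeric(1L),
        Kg = he_conv3(1L, cp), bg = numeric(1L),
        gg = rep(1, 1L), beg = numeric(1L)
      )
    }
    state <- list(
      accel = lapply(1:4, function(i)
        list(bn1 = init_bn_state(w[i]), bn3 = init_bn_state(w[i]))),
      gyro = lapply(1:4, function(i)
        list(bn1 = init_bn_state(w[i]), bn3 = init_bn_state(w[i])))
    )
    if (config$cmim_position != "none") {
      state$cmim <- list(bnj = init_bn_state(config$cmim_hidden),
                         bna = init_bn_state(1L),
                         bng = init_bn_state(1L))
    }
    structure(list(config = config, params = params, state = state),
              class = "cminet_model")
  })
}

#' Number of trainable parameters
#'
#' Counts weights, biases and batch-normalization affine parameters (running
#' statistics are state, not parameters).
#'
#' @param model A `cminet_model`.
#' @return Integer count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "cminet_model"))
  sum(unlist(rapply(model$params, length, how = "unlist")))
}

#' @export
print.cminet_model <- function(x, ...) {
  cat("<cminet_model>", paste(x$config$widths, collapse = "-"),
      "widths, attention:", x$config$cmim_position,
      sprintf("(%d parameters)\n", count_parameters(x)))
  invisible(x)
}

# ---- residual-like convolution block ---------------------------------------

# out = ReLU( BN(Conv1x1(X)) + BN(Conv1x3(X)) ); spatial dims preserved.
res_lcb_fwd <- function(X, p, st, training) {
  c1 <- conv1x1_fwd(X, p$K1, p$b1)
  n1 <- bn_fwd(c1$out, p$g1, p$be1, st$bn1, training)
  c3 <- conv1x3_fwd(X, p$K3, p$b3)
  n3 <- bn_fwd(c3$out, p$g3, p$be3, st$bn3, training)
  r <- relu_fwd(n1$out + n3$out)
  list(out = r$out,
       state = list(bn1 = n1$run, bn3 = n3$run),
       cache = list(c1 = c1$cache, n1 = n1$cache,
                    c3 = c3$cache, n3 = n3$cache, relu = r$cache))
}

res_lcb_bwd <- function(dY, cache) {
  dS <- relu_bwd(dY, cache$relu)
  b1 <- bn_bwd(dS, cache$n1)
  d1 <- conv1x1_bwd(b1$dX, cache$c1)
  b3 <- bn_bwd(dS, cache$n3)
  d3 <- conv1x3_bwd(b3$dX, cache$c3)
  list(dX = d1$dX + d3$dX,
       grads = list(K1 = d1$dK, b1 = d1$db, g1 = b1$dgamma, be1 = b1$dbeta,
                    K3 = d3$dK, b3 = d3$db, g3 = b3$dgamma, be3 = b3$dbeta))
}

#' Residual-like convolution block, standalone forward
#'
#' Computes `ReLU(BN(Conv1x1(X)) + BN(Conv1x3(X)))` on a single feature map.
#' The 1x3 convolution is zero-padded along time so spatial dimensions are
#' preserved; the channel count becomes the block width.
#'
#' @param X Numeric array `C x H x W` (channels, sensor axes, timesteps).
#' @param params List with 1x1-conv weights `K1` (`Cout x C`) and bias `b1`,
#'   1x3-conv weights `K3` (`Cout x C x 3`) and bias `b3`, and the two
#'   batch-norm affine pairs `g1, be1, g3, be3`.
#' @param state Optional batch-norm running statistics (`bn1`, `bn3`, each
#'   `list(mean, var)`); defaults to the neutral statistics (mean 0, var 1).
#' @param training If `TRUE` normalizes with batch statistics.
#' @return Numeric array `Cout x H x W`.
#' @export
res_lcb_forward <- function(X, params, state = NULL, training = FALSE) {
  stopifnot(is.array(X), length(dim(X)) == 3L)
  cout <- length(params$b1)
  if (is.null(state)) state <- list(bn1 = init_bn_state(cout),
                                    bn3 = init_bn_state(cout))
  Xi <- aperm(X, c(1L, 3L, 2L)) # C x W x H: treat axes as sequences
  out <- res_lcb_fwd(Xi, params, state, training)$out
  aperm(out, c(1L, 3L, 2L))
}

# ---- cross-modality interaction module -------------------------------------

# Channel-average both modality maps, fuse them through a 1x3 convolution
# into a joint representation, derive one sigmoid spatial attention map per
# modality from two independent heads, and recalibrate residually:
# A' = A * att_A + A  (so A' - A = A * att_A exactly, and the module can only
# amplify features by a factor in (1, 2), never null them).
cmim_fwd <- function(A, G, p, st, training) {
  dA <- dim(A)
  C <- dA[1L]; WN <- dA[2L] * dA[3L]
  mA <- colMeans(matrix(A, C, WN))
  mG <- colMeans(matrix(G, C, WN))
  J <- array(rbind(mA, mG), c(2L, dA[2L], dA[3L]))
  cj <- conv1x3_fwd(J, p$Kj, p$bj)
  nj <- bn_fwd(cj$out, p$gj, p$bej, st$bnj, training)
  rz <- relu_fwd(nj$out)
  Z <- rz$out
  ca <- conv1x3_fwd(Z, p$Ka, p$ba)
  na <- bn_fwd(ca$out, p$ga, p$bea, st$bna, training)
  attA <- sigmoid(na$out)
  cg <- conv1x3_fwd(Z, p$Kg, p$bg)
  ng <- bn_fwd(cg$out, p$gg, p$beg, st$bng, training)
  attG <- sigmoid(ng$out)
  sA <- rep(as.vector(attA), each = C)
  sG <- rep(as.vector(attG), each = C)
  Aref <- array(as.vector(A) * (1 + sA), dA)
  Gref <- array(as.vector(G) * (1 + sG), dA)
  list(A = Aref, G = Gref, attA = attA, attG = attG,
       state = list(bnj = nj$run, bna = na$run, bng = ng$run),
       cache = list(A = A, G = G, C = C, dA = dA,
                    cj = cj$cache, nj = nj$cache, relu = rz$cache,
                    ca = ca$cache, na = na$cache, attA = attA,
                    cg = cg$cache, ng = ng$cache, attG = attG))
}

cmim_bwd <- function(dAref, dGref, cache) {
  C <- cache$C; dA <- cache$dA
  WN <- dA[2L] * dA[3L]
  sA <- rep(as.vector(cache$attA), each = C)
  sG <- rep(as.vector(cache$attG), each = C)
  dAin <- array(as.vector(dAref) * (1 + sA), dA)
  dGin <- array(as.vector(dGref) * (1 + sG), dA)
  dattA <- array(colSums(matrix(as.vector(dAref) * as.vector(cache$A), C, WN)),
                 c(1L, dA[2L], dA[3L]))
  dattG <- array(colSums(matrix(as.vector(dGref) * as.vector(cache$G), C, WN)),
                 c(1L, dA[2L], dA[3L]))
  # through the sigmoids
  dna <- dattA * cache$attA * (1 - cache$attA)
  dng <- dattG * cache$attG * (1 - cache$attG)
  ba <- bn_bwd(dna, cache$na)
  da <- conv1x3_bwd(ba$dX, cache$ca)
  bg <- bn_bwd(dng, cache$ng)
  dg <- conv1x3_bwd(bg$dX, cache$cg)
  dZ <- da$dX + dg$dX
  dnj <- relu_bwd(dZ, cache$relu)
  bj <- bn_bwd(dnj, cache$nj)
  dj <- conv1x3_bwd(bj$dX, cache$cj)
  # split the joint input gradient back to the two channel-average maps
  dmA <- dj$dX[1L, , , drop = FALSE]
  dmG <- dj$dX[2L, , , drop = FALSE]
  dAin <- dAin + array(rep(as.vector(dmA), each = C) / C, dA)
  dGin <- dGin + array(rep(as.vector(dmG), each = C) / C, dA)
  list(dA = dAin, dG = dGin,
       grads = list(Kj = dj$dK, bj = dj$db, gj = bj$dgamma, bej = bj$dbeta,
                    Ka = da$dK, ba = da$db, ga = ba$dgamma, bea = ba$dbeta,
                    Kg = dg$dK, bg = dg$db, gg = bg$dgamma, beg = bg$dbeta))
}

#' Cross-modality interaction module, standalone forward
#'
#' Given same-shaped feature maps from the accelerometer and gyroscope trunks,
#' builds channel-average spatial maps of each, fuses them into a joint
#' representation through a 1x3 convolution (batch-normalized, ReLU), derives
#' one sigmoid spatial attention map per modality through two independent
#' convolution heads, and recalibrates each input residually:
#' `A' = A * att_A + A` and symmetrically for `G`.
#'
#' @param A,G Numeric arrays `C x H x W` of identical shape.
#' @param params Module weights: joint conv `Kj` (`C' x 2 x 3`) with bias
#'   `bj` and batch-norm pair `gj, bej`; accelerometer head `Ka`
#'   (`1 x C' x 3`), `ba`, `ga`, `bea`; gyroscope head `Kg`, `bg`, `gg`,
#'   `beg` (never shared with the accelerometer head).
#' @param state Optional batch-norm running statistics (`bnj`, `bna`, `bng`);
#'   defaults to neutral statistics.
#' @param training If `TRUE` normalizes with batch statistics.
#' @return List with refined maps `A` and `G` (same shapes as the inputs) and
#'   attention maps `att_accel`, `att_gyro` (`1 x H x W`, values in (0, 1)).
#' @export
cmim_forward <- function(A, G, params, state = NULL, training = FALSE) {
  stopifnot(is.array(A), is.array(G), identical(dim(A), dim(G)),
            length(dim(A)) == 3L)
  if (is.null(state)) state <- list(bnj = init_bn_state(length(params$bj)),
                                    bna = init_bn_state(1L),
                                    bng = init_bn_state(1L))
  Ai <- aperm(A, c(1L, 3L, 2L))
  Gi <- aperm(G, c(1L, 3L, 2L))
  r <- cmim_fwd(Ai, Gi, params, state, training)
  list(A = aperm(r$A, c(1L, 3L, 2L)),
       G = aperm(r$G, c(1L, 3L, 2L)),
       att_accel = aperm(r$attA, c(1L, 3L, 2L)),
       att_gyro = aperm(r$attG, c(1L, 3L, 2L)))
}

# ---- full network ----------------------------------------------------------

# Convert a batch (B x 3 x 200 array, or 3 x 200 matrix) to the internal
# (1, W, 3B) layout, axis-fastest.
batch_to_internal <- function(x) {
  if (is.matrix(x)) dim(x) <- c(1L, dim(x))
  stopifnot(length(dim(x)) == 3L, dim(x)[2L] == 3L)
  B <- dim(x)[1L]; W <- dim(x)[3L]
  y <- aperm(x, c(3L, 2L, 1L)) # W x 3 x B, w fastest then axis then sample
  dim(y) <- c(1L, W, 3L * B)
  y
}

# One trunk forward up to (and including) block4, inserting nothing; the CMIM
# is applied between stages by the caller.  Returns features after each stage.
trunk_stage_names <- function() {
  c("after_pool1", "after_pool2", "after_pool3", "after_block4")
}

model_forward_internal <- function(model, Xa, Xg, training = FALSE,
                                   keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  st <- model$state
  pos <- cfg$cmim_position
  # run both trunks stage by stage so the CMIM can splice in at its site
  stages <- trunk_stage_names()
  site <- match(pos, stages) # NA for "none"
  a <- list(cur = Xa, caches = list(), states = list())
  g <- list(cur = Xg, caches = list(), states = list())
  step <- function(s, branch, i) {
    blk <- res_lcb_fwd(s$cur, p[[branch]][[i]], st[[branch]][[i]], training)
    s$cur <- blk$out
    s$caches[[paste0("block", i)]] <- blk$cache
    s$states[[i]] <- blk$state
    if (i < 4L) {
      pl <- maxpool2_fwd(s$cur)
      s$cur <- pl$out
      s$caches[[paste0("pool", i)]] <- pl$cache
    }
    s
  }
  cmim_out <- NULL
  for (i in 1:4) {
    a <- step(a, "accel", i)
    g <- step(g, "gyro", i)
    if (!is.na(site) && site == i) {
      cm <- cmim_fwd(a$cur, g$cur, p$cmim, st$cmim, training)
      a$cur <- cm$A
      g$cur <- cm$G
      cmim_out <- cm
    }
  }

  ga_ <- gap_fwd(a$cur)
  gg_ <- gap_fwd(g$cur)
  fa <- fc_fwd(ga_$out, p$fc_accel$W, p$fc_accel$b)
  ra <- relu_fwd(fa$out)
  fg <- fc_fwd(gg_$out, p$fc_gyro$W, p$fc_gyro$b)
  rg <- relu_fwd(fg$out)
  concat <- rbind(ra$out, rg$out)
  jo <- fc_fwd(concat, p$joint$W, p$joint$b)
  logits <- jo$out # n_classes x B
  if (!all(is.finite(logits)))
    stop("non-finite logits produced at the joint fully connected layer")

  state_new <- st
  for (i in 1:4) {
    state_new$accel[[i]] <- a$states[[i]]
    state_new$gyro[[i]] <- g$states[[i]]
  }
  if (!is.null(cmim_out)) state_new$cmim <- cmim_out$state

  res <- list(logits = t(logits), state = state_new,
              attA = cmim_out$attA, attG = cmim_out$attG)
  if (keep_cache) {
    res$cache <- list(a = a, g = g, cmim = cmim_out, site = site,
                      gapA = ga_, gapG = gg_, fa = fa, ra = ra$cache,
                      fg = fg, rg = rg$cache, jo = jo,
                      fc_width = cfg$fc_width)
  }
  res
}

model_backward_internal <- function(model, fwd, dlogits) {
  cfg <- model$config
  ch <- fwd$cache
  dl <- t(dlogits) # n_classes x B
  djo <- fc_bwd(dl, ch$jo$cache)
  fcw <- ch$fc_width
  dra <- djo$dX[seq_len(fcw), , drop = FALSE]
  drg <- djo$dX[fcw + seq_len(fcw), , drop = FALSE]
  dfa <- fc_bwd(relu_bwd(dra, ch$ra), ch$fa$cache)
  dfg <- fc_bwd(relu_bwd(drg, ch$rg), ch$fg$cache)
  dXa <- gap_bwd(dfa$dX, ch$gapA$cache)
  dXg <- gap_bwd(dfg$dX, ch$gapG$cache)

  grads <- list(
    accel = vector("list", 4L), gyro = vector("list", 4L),
    fc_accel = list(W = dfa$dW, b = dfa$db),
    fc_gyro = list(W = dfg$dW, b = dfg$db),
    joint = list(W = djo$dW, b = djo$db)
  )
  site <- ch$site
  for (i in 4:1) {
    if (!is.na(site) && site == i) {
      cm <- cmim_bwd(dXa, dXg, ch$cmim$cache)
      dXa <- cm$dA
      dXg <- cm$dG
      grads$cmim <- cm$grads
    }
    if (i < 4L) {
      dXa <- maxpool2_bwd(dXa, ch$a$caches[[paste0("pool", i)]])
      dXg <- maxpool2_bwd(dXg, ch$g$caches[[paste0("pool", i)]])
    }
    ba <- res_lcb_bwd(dXa, ch$a$caches[[paste0("block", i)]])
    bg <- res_lcb_bwd(dXg, ch$g$caches[[paste0("block", i)]])
    grads$accel[[i]] <- ba$grads
    grads$gyro[[i]] <- bg$grads
    dXa <- ba$dX
    dXg <- bg$dX
  }
  grads
}

#' Forward pass of the classifier
#'
#' Deterministic in evaluation mode (batch-normalization uses running
#' statistics).  In training mode the model's running statistics are updated
#' and returned in the result; the caller decides whether to commit them.
#'
#' @param model A `cminet_model` from [build_model()].
#' @param accel,gyro Numeric `B x 3 x 200` arrays (or a single `3 x 200`
#'   matrix each), already standardized.
#' @param training Use batch statistics and update running statistics.
#' @return Matrix of logits, `B x n_classes`.
#' @export
model_forward <- function(model, accel, gyro, training = FALSE) {
  stopifnot(inherits(model, "cminet_model"))
  Xa <- batch_to_internal(accel)
  Xg <- batch_to_internal(gyro)
  model_forward_internal(model, Xa, Xg, training = training)$logits
}

#' Extract the attention maps at the interaction site
#'
#' Returns, per sample, the two sigmoid spatial attention maps the
#' interaction module produced; each value in (0, 1) is the contribution
#' degree of one (axis, temporal period) cell of that modality's features.
#'
#' @param model A `cminet_model` built with an attention module.
#' @param accel,gyro Standardized input batches as in [model_forward()].
#' @return List with arrays `accel` and `gyro` of dim `B x 3 x W_site`.
#' @export
extract_attention_maps <- function(model, accel, gyro) {
  stopifnot(inherits(model, "cminet_model"))
  if (model$config$cmim_position == "none")
    stop("model was built without a cross-modality interaction module")
  Xa <- batch_to_internal(accel)
  Xg <- batch_to_internal(gyro)
  fwd <- model_forward_internal(model, Xa, Xg, training = FALSE)
  reshape <- function(att) {
    W <- dim(att)[2L]; N <- dim(att)[3L]; B <- N %/% 3L
    dim(att) <- c(W, 3L, B) # w fastest, then axis, then sample
    aperm(att, c(3L, 2L, 1L))
  }
  list(accel = reshape(fwd$attA), gyro = reshape(fwd$attG))
}

#' Save / load a model checkpoint
#'
#' Serializes weights, running statistics and the build configuration in one
#' versioned file; loading validates their consistency.
#'
#' @param model A `cminet_model`.
#' @param path Checkpoint file path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cminet_model"))
  saveRDS(list(format = "cminet_checkpoint_v1",
               config = model$config, params = model$params,
               state = model$state), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "cminet_checkpoint_v1"))
    stop("not a recognized model checkpoint: ", path)
  model <- structure(list(config = x$config, params = x$params,
                          state = x$state), class = "cminet_model")
  ref <- build_model(x$config)
  same_shape <- function(a, b) identical(rapply(a, function(z) dim(z) %||% length(z), how = "list"),
                                         rapply(b, function(z) dim(z) %||% length(z), how = "list"))
  if (!same_shape(ref$params, model$params))
    stop("checkpoint weights do not match its configuration: ", path)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
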
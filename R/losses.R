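# Loss functions for imbalanced multiclass classification.
#
# All losses take a B x C logit matrix and integer labels in 1..C, return the
# batch mean by default, and can also return their analytic gradient with
# respect to the logits (used by the trainer and verified against finite
# differences in the test suite).

check_loss_inputs <- function(logits, labels) {
  stopifnot(is.matrix(logits), is.numeric(logits))
  if (!all(is.finite(logits))) stop("logits contain non-finite values")
  labels <- as.integer(labels)
  C <- ncol(logits)
  if (length(labels) != nrow(logits))
    stop("length(labels) must equal nrow(logits)")
  if (any(labels < 1L | labels > C))
    stop("labels must lie in 1..", C)
  labels
}

counts_for <- function(counts, labels, C) {
  counts <- unlist(counts)
  if (length(counts) != C)
    stop("class counts must have length ", C)
  n <- as.numeric(counts)[labels]
  if (any(!is.finite(n) | n < 1))
    stop("every class present in the batch needs a positive count")
  n
}

reduce_loss <- function(per_sample, reduction) {
  switch(reduction, mean = mean(per_sample), sum = sum(per_sample),
         stop("reduction must be 'mean' or 'sum'"))
}

reduction_scale <- function(reduction, B) if (reduction == "mean") 1 / B else 1

#' Softmax cross-entropy loss
#'
#' Per sample `-log softmax(z)[y]`, computed with log-sum-exp stabilization;
#' the batch mean is returned.
#'
#' @param logits Numeric `B x C` matrix of predicted logits.
#' @param labels Integer class indices in `1..C`.
#' @param reduction `"mean"` (default) or `"sum"` over the batch.
#' @param gradient If `TRUE`, return `list(value, gradient)` where the
#'   gradient is with respect to the logits.
#' @return Scalar loss, or the list when `gradient = TRUE`.
#' @export
softmax_ce <- function(logits, labels, reduction = "mean", gradient = FALSE) {
  labels <- check_loss_inputs(logits, labels)
  B <- nrow(logits)
  mx <- apply(logits, 1L, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  per <- lse - logits[cbind(seq_len(B), labels)]
  val <- reduce_loss(per, reduction)
  if (!gradient) return(val)
  p <- exp(logits - lse)
  p[cbind(seq_len(B), labels)] <- p[cbind(seq_len(B), labels)] - 1
  list(value = val, gradient = p * reduction_scale(reduction, B))
}

#' Class-balanced weight (reciprocal effective number of samples)
#'
#' The effective number of samples of a class with `n` observations is
#' `E_n = (1 - beta^n) / (1 - beta)`; this returns its reciprocal
#' `(1 - beta) / (1 - beta^n)`, the class-balancing weight.  It equals 1 at
#' `beta = 0` or `n = 1`, decreases strictly in both arguments otherwise, and
#' tends to `1/n` as `beta` approaches 1.
#'
#' @param n Positive integer class count(s); vectorized.
#' @param beta Smoothing hyperparameter in `[0, 1)` (0.9999 in the study
#'   protocol).
#' @return Numeric weight(s) in `(0, 1]`.
#' @export
cb_weight <- function(n, beta) {
  stopifnot(is.numeric(n), all(n >= 1), length(beta) == 1L)
  if (beta < 0 || beta >= 1)
    stop("beta must lie in [0, 1); use weights 1/n directly for the limit")
  if (beta == 0) return(rep(1, length(n)))
  # beta^n via exp(n * log1p(-(1-beta))) keeps precision for beta near 1
  (1 - beta) / -expm1(n * log1p(-(1 - beta)))
}

# Shared core of the sigmoid-focal family: logits of non-true classes are
# negated, each class contributes a one-vs-rest binary term
# -(1 - p)^gamma * log(p) with p = sigmoid of the transformed logit, and the
# per-sample sum is scaled by `w` (1 for plain focal loss, the class-balanced
# weight otherwise).
sigmoid_focal_core <- function(logits, labels, w, gamma, reduction, gradient) {
  B <- nrow(logits)
  sign_mat <- matrix(-1, B, ncol(logits))
  sign_mat[cbind(seq_len(B), labels)] <- 1
  zt <- logits * sign_mat
  logp <- stats::plogis(zt, log.p = TRUE)
  q <- stats::plogis(-zt) # 1 - p
  per <- -rowSums(q^gamma * logp) * w
  val <- reduce_loss(per, reduction)
  if (!gradient) return(val)
  p <- stats::plogis(zt)
  dzt <- if (gamma == 0) -q else gamma * p * q^gamma * logp - q^(gamma + 1)
  g <- dzt * sign_mat * w * reduction_scale(reduction, B)
  list(value = val, gradient = g)
}

#' Class-balanced focal loss
#'
#' The sigmoid (one-vs-rest) focal loss over all classes -- non-ground-truth
#' logits are negated, each class contributes
#' `-(1 - p_i)^gamma * log(p_i)` with `p_i` the sigmoid of the transformed
#' logit -- scaled per sample by the reciprocal effective number
#' [cb_weight()] of the ground-truth class.  With `beta = 0, gamma = 0` it
#' reduces to the plain summed sigmoid cross-entropy.
#'
#' @inheritParams softmax_ce
#' @param counts Per-class sample counts (length `C`, registry order), e.g.
#'   `class_distribution(train_segments)$counts`.
#' @param beta Class-balancing hyperparameter in `[0, 1)`; 0.9999 in the
#'   study protocol.
#' @param gamma Focusing hyperparameter `>= 0`; the study grid is
#'   `{0.5, 1, 2}` with 0.5 performing best.
#' @param normalize If `TRUE` (default), rescale the class weights to mean 1
#'   over classes (`w_c * C / sum(w_c)`), the convention of the reference
#'   class-balanced-loss implementation.  Relative class weighting is
#'   unchanged; the rescaling keeps the loss on the same scale as the
#'   unweighted losses so that optimizer settings and the L2 penalty act
#'   comparably across losses.  `FALSE` gives the raw reciprocal effective
#'   numbers.  At `beta = 0` the two are identical.
#' @return Scalar loss, or `list(value, gradient)`.
#' @export
cb_focal_loss <- function(logits, labels, counts, beta = 0.9999, gamma = 0.5,
                          normalize = TRUE, reduction = "mean",
                          gradient = FALSE) {
  labels <- check_loss_inputs(logits, labels)
  stopifnot(gamma >= 0)
  w <- cb_class_weights(counts, beta, ncol(logits), normalize)[labels]
  sigmoid_focal_core(logits, labels, w, gamma, reduction, gradient)
}

# Per-class CB weights over the whole registry, optionally mean-normalized.
cb_class_weights <- function(counts, beta, C, normalize) {
  n <- as.numeric(unlist(counts))
  if (length(n) != C) stop("class counts must have length ", C)
  if (any(!is.finite(n) | n < 1))
    stop("every class needs a positive count")
  w <- cb_weight(n, beta)
  if (normalize) w <- w * C / sum(w)
  w
}

#' Focal loss
#'
#' [cb_focal_loss()] with the class-balancing weight replaced by 1: a pure
#' sample-level reweighting that down-weights well-classified samples.
#'
#' @inheritParams cb_focal_loss
#' @return Scalar loss, or `list(value, gradient)`.
#' @export
focal_loss <- function(logits, labels, gamma = 0.5, reduction = "mean",
                       gradient = FALSE) {
  labels <- check_loss_inputs(logits, labels)
  stopifnot(gamma >= 0)
  sigmoid_focal_core(logits, labels, 1, gamma, reduction, gradient)
}

weighted_softmax_ce <- function(logits, labels, w, reduction, gradient) {
  B <- nrow(logits)
  mx <- apply(logits, 1L, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  per <- (lse - logits[cbind(seq_len(B), labels)]) * w
  val <- reduce_loss(per, reduction)
  if (!gradient) return(val)
  p <- exp(logits - lse)
  p[cbind(seq_len(B), labels)] <- p[cbind(seq_len(B), labels)] - 1
  list(value = val, gradient = p * w * reduction_scale(reduction, B))
}

#' Cost-sensitive cross-entropy loss
#'
#' Softmax cross-entropy with each sample weighted by the inverse frequency
#' of its class, `w_y = N / (C * n_y)`; balanced counts give weight 1
#' everywhere and recover [softmax_ce()].
#'
#' @inheritParams cb_focal_loss
#' @return Scalar loss, or `list(value, gradient)`.
#' @export
cs_ce_loss <- function(logits, labels, counts, reduction = "mean",
                       gradient = FALSE) {
  labels <- check_loss_inputs(logits, labels)
  C <- ncol(logits)
  n_y <- counts_for(counts, labels, C)
  w <- sum(unlist(counts)) / (C * n_y)
  weighted_softmax_ce(logits, labels, w, reduction, gradient)
}

#' Class-balanced cross-entropy loss
#'
#' Softmax cross-entropy with each sample weighted by the reciprocal
#' effective number [cb_weight()] of its class (mean-normalized over classes
#' by default, see [cb_focal_loss()]); `beta = 0` recovers [softmax_ce()],
#' and `beta -> 1` approaches inverse-count weighting.
#'
#' @inheritParams cb_focal_loss
#' @return Scalar loss, or `list(value, gradient)`.
#' @export
cb_ce_loss <- function(logits, labels, counts, beta = 0.9999,
                       normalize = TRUE, reduction = "mean",
                       gradient = FALSE) {
  labels <- check_loss_inputs(logits, labels)
  w <- cb_class_weights(counts, beta, ncol(logits), normalize)[labels]
  weighted_softmax_ce(logits, labels, w, reduction, gradient)
}

#' Adaptive class suppression loss
#'
#' A sigmoid cross-entropy over classes in which the ground-truth term keeps
#' weight 1 while a non-ground-truth class `i` is weighted 1 when
#' `n_i >= n_y` (confusions toward commoner classes stay fully penalized)
#' and by the predicted confidence `p_i^gamma` when class `i` is rarer than
#' the ground truth, so rare classes are suppressed only where the network
#' actually confuses them.  This class-count-and-confidence gating is the
#' standard form of the adaptive suppression family, restated here for flat
#' multiclass classification; the analytic gradient differentiates through
#' the confidence gate, so it is exact for the stated objective.
#'
#' @inheritParams cb_focal_loss
#' @param gamma Confidence-gating exponent, default 2.
#' @return Scalar loss, or `list(value, gradient)`.
#' @export
acs_loss <- function(logits, labels, counts, gamma = 2, reduction = "mean",
                     gradient = FALSE) {
  labels <- check_loss_inputs(logits, labels)
  B <- nrow(logits)
  C <- ncol(logits)
  counts_for(counts, labels, C) # validates positivity
  n <- as.numeric(unlist(counts))
  n_y <- n[labels]
  p <- stats::plogis(logits)
  # weights: 1 on the true class and on commoner classes, p_i^gamma on rarer
  common <- matrix(n, B, C, byrow = TRUE) >= n_y
  w <- ifelse(common, 1, p^gamma)
  true_idx <- cbind(seq_len(B), labels)
  w[true_idx] <- 1
  log1mp <- stats::plogis(-logits, log.p = TRUE) # log(1 - p_i)
  term <- -w * log1mp
  term[true_idx] <- -stats::plogis(logits, log.p = TRUE)[true_idx]
  per <- rowSums(term)
  val <- reduce_loss(per, reduction)
  if (!gradient) return(val)
  # d/dz of -log(1-p) is p; the confidence gate adds its own chain term
  # d/dz[-p^g log(1-p)] = p^(g+1) - g p^g (1-p) log(1-p)
  g <- w * p
  gated <- !common
  gated[true_idx] <- FALSE
  if (gamma > 0 && any(gated)) {
    pg <- p[gated]
    g[gated] <- g[gated] - gamma * pg^gamma * (1 - pg) * log1mp[gated]
  }
  g[true_idx] <- -(1 - p[true_idx])
  list(value = val, gradient = g * reduction_scale(reduction, B))
}

#' Resolve a loss specification to a closure
#'
#' Maps a configuration string to the matching loss with its hyperparameters
#' and class counts bound, as used by the training protocol and the
#' experiment runner.
#'
#' @param name One of `"softmax_ce"`, `"focal"`, `"cs_ce"`, `"cb_ce"`,
#'   `"acs"`, `"cb_focal"`.
#' @param counts Per-class training counts (required by all but
#'   `"softmax_ce"` and `"focal"`).
#' @param beta,gamma Hyperparameters forwarded where applicable; when `gamma`
#'   is `NULL` it defaults to 0.5 (the study's best focal setting) except for
#'   `"acs"`, whose canonical default is 2.
#' @return `function(logits, labels, gradient = FALSE)`.
#' @export
make_loss <- function(name, counts = NULL, beta = 0.9999, gamma = NULL) {
  name <- match.arg(name, c("softmax_ce", "focal", "cs_ce", "cb_ce", "acs",
                            "cb_focal"))
  if (is.null(gamma)) gamma <- if (name == "acs") 2 else 0.5
  needs_counts <- !name %in% c("softmax_ce", "focal")
  if (needs_counts && is.null(counts))
    stop("loss '", name, "' requires per-class counts")
  switch(name,
    softmax_ce = function(logits, labels, gradient = FALSE)
      softmax_ce(logits, labels, gradient = gradient),
    focal = function(logits, labels, gradient = FALSE)
      focal_loss(logits, labels, gamma = gamma, gradient = gradient),
    cs_ce = function(logits, labels, gradient = FALSE)
      cs_ce_loss(logits, labels, counts, gradient = gradient),
    cb_ce = function(logits, labels, gradient = FALSE)
      cb_ce_loss(logits, labels, counts, beta = beta, gradient = gradient),
    acs = function(logits, labels, gradient = FALSE)
      acs_loss(logits, labels, counts, gamma = gamma, gradient = gradient),
    cb_focal = function(logits, labels, gradient = FALSE)
      cb_focal_loss(logits, labels, counts, beta = beta, gamma = gamma,
                    gradient = gradient))
}
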
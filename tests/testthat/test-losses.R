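# Independent brute-force oracles, written against the formulas directly and
# kept free of the package's vectorized implementations.

brute_softmax_ce <- function(z, y) {
  mean(vapply(seq_len(nrow(z)), function(i) {
    p <- exp(z[i, ]) / sum(exp(z[i, ]))
    -log(p[y[i]])
  }, 0))
}

# sign-flipped sigmoid focal term, one sample
brute_focal_sample <- function(z_i, y_i, gamma) {
  s <- 0
  for (j in seq_along(z_i)) {
    zt <- if (j == y_i) z_i[j] else -z_i[j]
    p <- 1 / (1 + exp(-zt))
    s <- s - (1 - p)^gamma * log(p)
  }
  s
}

brute_cb_focal <- function(z, y, counts, beta, gamma) {
  wc <- vapply(counts, function(n)
    if (beta == 0) 1 else (1 - beta) / (1 - beta^n), 0)
  wc <- wc * length(wc) / sum(wc) # mean-1 normalization over classes
  mean(vapply(seq_len(nrow(z)), function(i)
    wc[y[i]] * brute_focal_sample(z[i, ], y[i], gamma), 0))
}

random_inputs <- function(B = 8, C = 6, seed) {
  withr::with_seed(seed, list(z = matrix(rnorm(B * C, sd = 2), B, C),
                              y = sample.int(C, B, replace = TRUE)))
}

cnt6 <- function(v = c(200L, 18L, 60L, 120L, 9L, 400L)) {
  stats::setNames(as.integer(v), activity_classes())
}

test_that("softmax cross-entropy matches its definition and limits", {
  expect_equal(softmax_ce(matrix(0, 3, 6), c(1L, 4L, 6L)), log(6),
               tolerance = 1e-12)
  z <- matrix(0, 1, 6)
  z[1, 2] <- 60 # near-certain correct prediction
  expect_lt(softmax_ce(z, 2L), 1e-12)
  for (seed in 1:5) {
    ri <- random_inputs(B = 4, seed = seed)
    expect_equal(softmax_ce(ri$z, ri$y), brute_softmax_ce(ri$z, ri$y),
                 tolerance = 1e-6)
  }
})

test_that("class-balanced weight obeys its closed form and limits", {
  expect_equal(cb_weight(c(1, 7, 5000), 0), c(1, 1, 1))
  expect_equal(cb_weight(1, 0.73), 1)
  # high-precision oracle for the study's beta
  n <- 10000
  expect_equal(cb_weight(n, 0.9999), 1e-4 / (1 - 0.9999^n), tolerance = 1e-10)
  # strictly decreasing in n and in beta
  w <- cb_weight(1:100, 0.95)
  expect_true(all(diff(w) < 0))
  wb <- vapply(c(0.5, 0.9, 0.99, 0.9999), function(b) cb_weight(10, b), 0)
  expect_true(all(diff(wb) < 0))
  # beta -> 1 limit is 1/n
  n <- 1:10000
  expect_lt(max(abs(cb_weight(n, 1 - 1e-8) * n - 1)), 1e-4)
  expect_error(cb_weight(5, 1), "beta")
})

test_that("class-balanced focal loss matches the brute-force oracle", {
  # z = 0: every transformed p is 1/2, so each class contributes ln 2
  expect_equal(cb_focal_loss(matrix(0, 2, 6), c(3L, 5L), cnt6(),
                             beta = 0, gamma = 0),
               6 * log(2), tolerance = 1e-12)
  for (seed in 1:8) {
    ri <- random_inputs(seed = seed)
    for (gamma in c(0, 0.5, 1, 2)) {
      expect_equal(
        cb_focal_loss(ri$z, ri$y, cnt6(), beta = 0.9999, gamma = gamma),
        brute_cb_focal(ri$z, ri$y, cnt6(), 0.9999, gamma),
        tolerance = 1e-8)
    }
    expect_equal(cb_focal_loss(ri$z, ri$y, cnt6(), beta = 0, gamma = 0),
                 brute_cb_focal(ri$z, ri$y, cnt6(), 0, 0),
                 tolerance = 1e-8)
  }
})

test_that("raising the true-class logit or its class count lowers the loss", {
  ri <- random_inputs(seed = 3)
  z2 <- ri$z
  z2[cbind(seq_len(8), ri$y)] <- z2[cbind(seq_len(8), ri$y)] + 0.3
  expect_lt(cb_focal_loss(z2, ri$y, cnt6(), gamma = 0.5),
            cb_focal_loss(ri$z, ri$y, cnt6(), gamma = 0.5))
  # doubling the true class's count lowers that sample's loss
  z1 <- ri$z[1, , drop = FALSE]
  y1 <- ri$y[1]
  grown <- cnt6()
  grown[y1] <- grown[y1] * 2L
  expect_lt(cb_focal_loss(z1, y1, grown, beta = 0.9999),
            cb_focal_loss(z1, y1, cnt6(), beta = 0.9999))
  # without normalization the raw reciprocal effective number applies
  expect_equal(cb_focal_loss(z1, y1, cnt6(), beta = 0.9999, gamma = 0,
                             normalize = FALSE),
               cb_weight(cnt6()[[y1]], 0.9999) *
                 brute_focal_sample(ri$z[1, ], y1, 0),
               tolerance = 1e-10)
})

test_that("focal loss is the unweighted special case and rewards confidence", {
  ri <- random_inputs(seed = 9)
  expect_equal(focal_loss(ri$z, ri$y, gamma = 0.7),
               cb_focal_loss(ri$z, ri$y, cnt6(), beta = 0, gamma = 0.7),
               tolerance = 1e-12)
  # gamma = 0 is plain summed sigmoid CE
  expect_equal(focal_loss(ri$z, ri$y, gamma = 0),
               brute_cb_focal(ri$z, ri$y, cnt6(), 0, 0), tolerance = 1e-8)
  # a well-classified sample scores below the all-zero logits sample
  z_good <- matrix(-4, 1, 6)
  z_good[1, 2] <- 4
  expect_lt(focal_loss(z_good, 2L, gamma = 0.5),
            focal_loss(matrix(0, 1, 6), 2L, gamma = 0.5))
})

test_that("cost-sensitive CE weights samples by inverse class frequency", {
  ri <- random_inputs(seed = 4)
  balanced <- cnt6(rep(60L, 6))
  expect_equal(cs_ce_loss(ri$z, ri$y, balanced),
               softmax_ce(ri$z, ri$y), tolerance = 1e-12)
  # counts {90, 10}: minority weight is 5x majority weight
  z <- matrix(rnorm(4), 2, 2)
  w_major <- 100 / (2 * 90)
  w_minor <- 100 / (2 * 10)
  expect_equal(w_minor / w_major, 9)
  expect_equal(cs_ce_loss(z, c(1L, 2L), c(90L, 10L)),
               mean(c(w_major * brute_softmax_ce(z[1, , drop = FALSE], 1L),
                      w_minor * brute_softmax_ce(z[2, , drop = FALSE], 2L))),
               tolerance = 1e-8)
  expect_error(cs_ce_loss(ri$z, ri$y, cnt6(c(0L, 1L, 1L, 1L, 1L, 1L))),
               "positive count")
})

test_that("class-balanced CE interpolates between plain CE and 1/n weighting", {
  ri <- random_inputs(seed = 5)
  expect_equal(cb_ce_loss(ri$z, ri$y, cnt6(), beta = 0),
               softmax_ce(ri$z, ri$y), tolerance = 1e-12)
  near1 <- cb_ce_loss(ri$z, ri$y, cnt6(), beta = 1 - 1e-8)
  wlim <- 1 / as.numeric(cnt6()) # beta -> 1 limit is inverse counts
  wlim <- wlim * 6 / sum(wlim)
  per <- vapply(seq_len(8), function(i)
    brute_softmax_ce(ri$z[i, , drop = FALSE], ri$y[i]) * wlim[ri$y[i]], 0)
  expect_equal(near1, mean(per), tolerance = 1e-3)
})

test_that("adaptive class suppression gates rare-class suppression by confidence", {
  ri <- random_inputs(seed = 6)
  balanced <- cnt6(rep(60L, 6))
  # equal counts and gamma = 0: every weight is 1 -> summed sigmoid CE
  expect_equal(acs_loss(ri$z, ri$y, balanced, gamma = 0),
               brute_cb_focal(ri$z, ri$y, balanced, 0, 0), tolerance = 1e-8)
  # brute-force agreement with the stated weighting rule
  brute_acs <- function(z, y, counts, gamma) {
    mean(vapply(seq_len(nrow(z)), function(i) {
      s <- 0
      for (j in seq_len(ncol(z))) {
        p <- 1 / (1 + exp(-z[i, j]))
        if (j == y[i]) {
          s <- s - log(p)
        } else {
          w <- if (counts[j] >= counts[y[i]]) 1 else p^gamma
          s <- s - w * log(1 - p)
        }
      }
      s
    }, 0))
  }
  expect_equal(acs_loss(ri$z, ri$y, cnt6(), gamma = 2),
               brute_acs(ri$z, ri$y, cnt6(), 2), tolerance = 1e-8)
  # a rare wrong class predicted with near-zero confidence contributes ~0
  z <- matrix(c(3, -15, 0, 0, 0, 0), 1, 6)
  cnts <- cnt6(c(600L, 2L, 60L, 60L, 60L, 60L))
  with_term <- acs_loss(z, 1L, cnts, gamma = 2)
  z2 <- z
  z2[1, 2] <- -30 # even more confident rejection changes nothing measurable
  expect_equal(with_term, acs_loss(z2, 1L, cnts, gamma = 2), tolerance = 1e-9)
})

test_that("every loss is finite, non-negative and batch-order equivariant", {
  loss_names <- c("softmax_ce", "focal", "cs_ce", "cb_ce", "acs", "cb_focal")
  for (seed in 1:3) {
    ri <- random_inputs(B = 12, seed = 20 + seed)
    perm <- withr::with_seed(seed, sample.int(12))
    for (nm in loss_names) {
      f <- make_loss(nm, counts = cnt6())
      v <- f(ri$z, ri$y)
      expect_true(is.finite(v))
      expect_gte(v, 0)
      expect_equal(f(ri$z[perm, ], ri$y[perm]), v, tolerance = 1e-12)
    }
  }
})

test_that("analytic gradients match central finite differences", {
  for (nm in c("softmax_ce", "focal", "cs_ce", "cb_ce", "acs", "cb_focal")) {
    f <- make_loss(nm, counts = cnt6())
    ri <- random_inputs(B = 4, seed = 31)
    g <- f(ri$z, ri$y, gradient = TRUE)
    expect_equal(g$value, f(ri$z, ri$y), tolerance = 1e-12)
    h <- 1e-5
    fd <- ri$z * 0
    for (i in seq_len(nrow(ri$z))) {
      for (j in seq_len(ncol(ri$z))) {
        zp <- ri$z; zp[i, j] <- zp[i, j] + h
        zm <- ri$z; zm[i, j] <- zm[i, j] - h
        fd[i, j] <- (f(zp, ri$y) - f(zm, ri$y)) / (2 * h)
      }
    }
    expect_equal(g$gradient, fd, tolerance = 1e-4)
  }
})

test_that("focal modulation orders the study's gamma grid consistently", {
  ri <- random_inputs(seed = 12)
  vals <- vapply(c(0, 0.5, 1, 2), function(g)
    cb_focal_loss(ri$z, ri$y, cnt6(), beta = 0.9999, gamma = g), 0)
  # (1-p)^gamma <= 1 shrinks every term, so the loss decreases in gamma
  expect_true(all(diff(vals) < 0))
  # and is continuous in gamma
  expect_equal(cb_focal_loss(ri$z, ri$y, cnt6(), gamma = 0.5),
               cb_focal_loss(ri$z, ri$y, cnt6(), gamma = 0.5 + 1e-9),
               tolerance = 1e-7)
})

test_that("loss inputs are validated", {
  z <- matrix(0, 2, 6)
  expect_error(softmax_ce(z, c(1L, 7L)), "labels")
  expect_error(softmax_ce(matrix(c(1, NA), 1, 2), 1L), "non-finite")
  expect_error(cb_focal_loss(z, c(1L, 2L), counts = 1:3), "length 6")
  expect_error(make_loss("cb_focal"), "counts")
  expect_error(make_loss("nope"), "arg")
})
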
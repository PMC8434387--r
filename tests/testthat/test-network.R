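neutral_block <- function(cin, cout) {
  # 1x1 branch = identity mapping, 1x3 branch zeroed, batch norm neutral
  list(K1 = diag(1, cout, cin), b1 = numeric(cout),
       g1 = rep(1, cout), be1 = numeric(cout),
       K3 = array(0, c(cout, cin, 3)), b3 = numeric(cout),
       g3 = rep(1, cout), be3 = numeric(cout))
}

test_that("residual-like block obeys its algebraic contracts", {
  C <- 4
  X <- withr::with_seed(1, array(rnorm(C * 3 * 20), c(C, 3, 20)))
  p <- neutral_block(C, C)
  # zero input, zero biases -> zero output
  expect_equal(res_lcb_forward(array(0, dim(X)), p), array(0, dim(X)))
  # identity 1x1 branch, zeroed 1x3 branch, neutral BN -> ReLU(X)
  out <- res_lcb_forward(X, p)
  expect_equal(out, array(pmax(X, 0), dim(X)), tolerance = 1e-4)
  # outputs are never negative, for random weights too
  pr <- withr::with_seed(2, list(
    K1 = matrix(rnorm(6 * C), 6, C), b1 = rnorm(6),
    g1 = runif(6, 0.5, 2), be1 = rnorm(6),
    K3 = array(rnorm(6 * C * 3), c(6, C, 3)), b3 = rnorm(6),
    g3 = runif(6, 0.5, 2), be3 = rnorm(6)))
  out2 <- res_lcb_forward(X, pr)
  expect_true(all(out2 >= 0))
  expect_identical(dim(out2), c(6L, 3L, 20L)) # spatial dims preserved
})

random_cmim_params <- function(cp = 3, seed = 5) {
  withr::with_seed(seed, list(
    Kj = array(rnorm(cp * 2 * 3), c(cp, 2, 3)), bj = rnorm(cp),
    gj = runif(cp, 0.5, 2), bej = rnorm(cp),
    Ka = array(rnorm(cp * 3), c(1, cp, 3)), ba = rnorm(1),
    ga = runif(1, 0.5, 2), bea = rnorm(1),
    Kg = array(rnorm(cp * 3), c(1, cp, 3)), bg = rnorm(1),
    gg = runif(1, 0.5, 2), beg = rnorm(1)))
}

test_that("interaction module recalibrates residually with sigmoid maps", {
  C <- 5
  A <- withr::with_seed(3, array(rnorm(C * 3 * 16), c(C, 3, 16)))
  G <- withr::with_seed(4, array(rnorm(C * 3 * 16), c(C, 3, 16)))
  p <- random_cmim_params()
  r <- cmim_forward(A, G, p)
  # shapes conserved; attention maps in (0, 1)
  expect_identical(dim(r$A), dim(A))
  expect_identical(dim(r$G), dim(G))
  expect_identical(dim(r$att_accel), c(1L, 3L, 16L))
  expect_true(all(r$att_accel > 0 & r$att_accel < 1))
  expect_true(all(r$att_gyro > 0 & r$att_gyro < 1))
  # residual identity: A' - A = A * att_A exactly (attention broadcast)
  att_b <- array(rep(as.vector(aperm(r$att_accel, c(1, 3, 2))), each = C),
                 c(C, 16, 3))
  expect_equal(aperm(r$A - A, c(1, 3, 2)),
               aperm(A, c(1, 3, 2)) * att_b, tolerance = 1e-12)
  # hence signs are preserved and magnitudes amplified by 1x..2x
  nz <- A != 0
  expect_true(all(sign(r$A[nz]) == sign(A[nz])))
  expect_true(all(abs(r$A[nz]) > abs(A[nz]) & abs(r$A[nz]) < 2 * abs(A[nz])))
})

test_that("zeroed attention heads give maps of exactly one half", {
  C <- 4
  A <- withr::with_seed(6, array(rnorm(C * 3 * 8), c(C, 3, 8)))
  G <- withr::with_seed(7, array(rnorm(C * 3 * 8), c(C, 3, 8)))
  p <- random_cmim_params(cp = 2)
  p$Ka[] <- 0; p$ba[] <- 0; p$bea[] <- 0
  p$Kg[] <- 0; p$bg[] <- 0; p$beg[] <- 0
  r <- cmim_forward(A, G, p)
  expect_equal(as.vector(r$att_accel), rep(0.5, 24))
  expect_equal(r$A, 1.5 * A, tolerance = 1e-12)
  expect_equal(r$G, 1.5 * G, tolerance = 1e-12)
})

test_that("a constant feature map has a constant channel-average map", {
  C <- 3
  A <- array(2.5, c(C, 3, 10))
  G <- array(-1, c(C, 3, 10))
  p <- random_cmim_params()
  r <- cmim_forward(A, G, p)
  # constant inputs + constant joint map -> spatially near-constant attention
  # away from the zero-padded temporal borders
  interior <- r$att_accel[1, , 3:8]
  expect_lt(max(interior) - min(interior), 1e-12)
})

test_that("the model assembles to the documented shapes and sizes", {
  cfg <- tiny_model_config()
  m <- build_model(cfg)
  b <- random_batch(4)
  lg <- model_forward(m, b$accel, b$gyro)
  expect_identical(dim(lg), c(4L, 6L))
  expect_true(all(is.finite(lg)))
  # single segment input
  lg1 <- model_forward(m, b$accel[1, , ], b$gyro[1, , ])
  expect_equal(lg1[1, ], lg[1, ], tolerance = 1e-12)
  # temporal extent halves at each pooling stage: 200 -> 100 -> 50 -> 25
  sizes <- c(after_pool1 = 100L, after_pool2 = 50L, after_pool3 = 25L,
             after_block4 = 25L)
  for (pos in names(sizes)) {
    mp <- build_model(tiny_model_config(cmim_position = pos))
    att <- extract_attention_maps(mp, b$accel, b$gyro)
    expect_identical(dim(att$accel), c(4L, 3L, sizes[[pos]]))
    expect_true(all(att$accel > 0 & att$accel < 1))
    expect_true(all(att$gyro > 0 & att$gyro < 1))
  }
})

test_that("an attention-free build carries no interaction parameters", {
  m_none <- build_model(tiny_model_config(cmim_position = "none"))
  m_full <- build_model(tiny_model_config())
  expect_null(m_none$params$cmim)
  cmim_n <- sum(vapply(m_full$params$cmim, length, 0L))
  expect_identical(count_parameters(m_full),
                   count_parameters(m_none) + cmim_n)
  expect_error(extract_attention_maps(m_none, random_batch(2)$accel,
                                      random_batch(2)$gyro), "without")
})

test_that("variants share identical trunk weights under one seed", {
  m_none <- build_model(tiny_model_config(cmim_position = "none"))
  for (pos in c("after_pool1", "after_pool3", "after_block4")) {
    mv <- build_model(tiny_model_config(cmim_position = pos))
    expect_identical(mv$params$accel, m_none$params$accel)
    expect_identical(mv$params$gyro, m_none$params$gyro)
    expect_identical(mv$params$joint, m_none$params$joint)
  }
})

test_that("evaluation-mode forward is deterministic and batch-equivariant", {
  m <- build_model(tiny_model_config())
  b <- random_batch(6, seed = 2)
  l1 <- model_forward(m, b$accel, b$gyro)
  l2 <- model_forward(m, b$accel, b$gyro)
  expect_identical(l1, l2)
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)
  l3 <- model_forward(m, b$accel[perm, , ], b$gyro[perm, , ])
  expect_equal(l3, l1[perm, ], tolerance = 1e-12)
})

test_that("backpropagation matches finite differences through the full model", {
  cfg <- tiny_model_config(cmim_position = "after_pool2")
  m <- build_model(cfg)
  b <- random_batch(3, seed = 7)
  y <- c(1L, 4L, 6L)
  Xa <- cminet:::batch_to_internal(b$accel)
  Xg <- cminet:::batch_to_internal(b$gyro)
  fwd <- cminet:::model_forward_internal(m, Xa, Xg, training = TRUE,
                                         keep_cache = TRUE)
  lo <- softmax_ce(fwd$logits, y, gradient = TRUE)
  grads <- cminet:::model_backward_internal(m, fwd, lo$gradient)
  loss_of <- function(model) {
    f <- cminet:::model_forward_internal(model, Xa, Xg, training = TRUE)
    softmax_ce(f$logits, y)
  }
  # probe a representative parameter of every layer type and location
  probes <- list(c("accel", 1L, "K3"), c("accel", 3L, "g1"),
                 c("gyro", 2L, "K1"), c("gyro", 4L, "be3"),
                 c("cmim", "Kj"), c("cmim", "Ka"), c("cmim", "gg"),
                 c("fc_accel", "W"), c("joint", "W"), c("joint", "b"))
  h <- 1e-5
  for (pr in probes) {
    pr <- as.list(pr)
    pr[vapply(pr, function(x) grepl("^[0-9]+$", x), TRUE)] <-
      lapply(pr[vapply(pr, function(x) grepl("^[0-9]+$", x), TRUE)],
             as.integer)
    leaf <- m$params
    g <- grads
    for (k in pr) {
      leaf <- leaf[[k]]
      g <- g[[k]]
    }
    for (i in unique(c(1L, length(leaf) %/% 2L + 1L, length(leaf)))) {
      m2 <- m
      leaf2 <- leaf
      leaf2[i] <- leaf[i] + h
      m2$params <- set_in_tree(m$params, pr, leaf2)
      up <- loss_of(m2)
      leaf2[i] <- leaf[i] - h
      m2$params <- set_in_tree(m$params, pr, leaf2)
      dn <- loss_of(m2)
      fd <- (up - dn) / (2 * h)
      expect_equal(g[i], fd, tolerance = 1e-3,
                   label = paste0("grad[", paste(unlist(pr), collapse = "/"),
                                  "][", i, "]"))
    }
  }
  # gradient flow: every parameter tensor receives some gradient
  flat <- rapply(grads, function(x) max(abs(x)), how = "unlist")
  expect_true(all(flat > 0))
})

test_that("checkpoints round-trip and validate their configuration", {
  m <- build_model(tiny_model_config())
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  b <- random_batch(2, seed = 5)
  expect_identical(model_forward(m2, b$accel, b$gyro),
                   model_forward(m, b$accel, b$gyro))
  saveRDS(list(format = "other"), path)
  expect_error(load_model(path), "not a recognized")
})

test_that("model configuration rejects invalid settings", {
  expect_error(model_config(cmim_position = "after_gap"), "arg")
  expect_error(model_config(widths = c(4, 8)), "length")
  expect_error(model_config(fc_width = 0), "fc_width")
})
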
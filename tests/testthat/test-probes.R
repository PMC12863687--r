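test_that("clip loss matches its analytic anchors", {
  set.seed(81)
  d <- 8L
  W <- diag(1, 4L, d)
  # N = 1: softmax over one class
  X1 <- matrix(rnorm(d), 1, d)
  expect_equal(clip_loss(X1, X1, W, tau = 0.07), 0)
  # tau -> Inf: uniform similarities, loss -> ln N
  X <- matrix(rnorm(8 * d), 8, d); Y <- matrix(rnorm(8 * d), 8, d)
  expect_equal(clip_loss(X, Y, W, tau = 1e6), log(8), tolerance = 1e-3)
  # constant S (identical rows): loss equals ln N exactly
  Xc <- matrix(rep(rnorm(d), each = 5), 5, d)
  Yc <- matrix(rep(rnorm(d), each = 5), 5, d)
  expect_equal(clip_loss(Xc, Yc, W, tau = 0.07), log(5), tolerance = 1e-9)
  # hand-computed N = 2 identity case at tau = 1: -ln(e/(e+1))
  X2 <- rbind(c(1, 0), c(0, 1))
  W2 <- diag(2)
  expect_equal(clip_loss(X2, X2, W2, tau = 1), -log(exp(1) / (exp(1) + 1)),
               tolerance = 1e-9)
  expect_equal(clip_loss(X2, X2, W2, tau = 1), 0.3133, tolerance = 1e-3)
  # non-negativity on random inputs
  for (i in 1:10) {
    expect_gte(clip_loss(matrix(rnorm(6 * d), 6, d),
                         matrix(rnorm(6 * d), 6, d),
                         matrix(rnorm(3 * d), 3, d), tau = 0.5), 0)
  }
  expect_error(clip_loss(X * 0, Y, W, tau = 1), "zero-norm")
})

test_that("clip gradients match finite differences", {
  set.seed(82)
  d <- 6L; k <- 3L; N <- 5L
  X <- matrix(rnorm(N * d), N, d); Y <- matrix(rnorm(N * d), N, d)
  W <- matrix(rnorm(k * d, 0, 0.5), k, d)
  Wy <- matrix(rnorm(k * d, 0, 0.5), k, d)
  for (dual in c(FALSE, TRUE)) {
    g <- clip_loss(X, Y, W, tau = 0.3, Wy = if (dual) Wy else NULL,
                   grads = TRUE)
    eps <- 1e-6
    for (i in sample(length(W), 5)) {
      Wp <- W; Wp[i] <- Wp[i] + eps
      Wm <- W; Wm[i] <- Wm[i] - eps
      num <- (clip_loss(X, Y, Wp, 0.3, if (dual) Wy else NULL) -
                clip_loss(X, Y, Wm, 0.3, if (dual) Wy else NULL)) / (2 * eps)
      expect_equal(g$dW[i], num, tolerance = 1e-5)
    }
    if (dual) {
      for (i in sample(length(Wy), 5)) {
        Wp <- Wy; Wp[i] <- Wp[i] + eps
        Wm <- Wy; Wm[i] <- Wm[i] - eps
        num <- (clip_loss(X, Y, W, 0.3, Wp) -
                  clip_loss(X, Y, W, 0.3, Wm)) / (2 * eps)
        expect_equal(g$dWy[i], num, tolerance = 1e-5)
      }
    }
  }
})

test_that("probe training recovers degenerate alignment and rejects bad input", {
  set.seed(83)
  d <- 96L; N <- 120L
  Z <- matrix(rnorm(N * d), N, d)
  r <- train_probe(Z, Z, "joint_single_W", train_frac = 0.05, steps = 400L,
                   seed = 83L)
  expect_gt(r$auroc, 0.95)
  expect_gt(mean(r$matched), 0.9)       # X == Y: matched similarity near 1
  # independent Gaussians: no shared structure, AUROC near chance
  Xg <- matrix(rnorm(N * d), N, d); Yg <- matrix(rnorm(N * d), N, d)
  r0 <- train_probe(Xg, Yg, "dual_W_control", train_frac = 0.05,
                    steps = 400L, seed = 83L)
  expect_lt(abs(r0$auroc - 0.5), 0.12)
  # backbone embeddings are never mutated
  Xc <- Xg; Yc <- Yg
  invisible(train_probe(Xg, Yg, "joint_single_W", steps = 50L, seed = 1L))
  expect_identical(Xg, Xc); expect_identical(Yg, Yc)
  expect_error(train_probe(Xg[1:2, ], Yg[1:2, ], train_frac = 0.5),
               "at least 2")
  expect_error(train_probe(Xg, Yg, k = 32L), "k < d/4")
})

test_that("the probe generalization gap shrinks with training fraction", {
  set.seed(84)
  d <- 96L; N <- 200L
  Z <- matrix(rnorm(N * 12L), N, 12L)
  mixx <- matrix(rnorm(12L * d, 0, 0.3), 12L, d)
  mixy <- matrix(rnorm(12L * d, 0, 0.3), 12L, d)
  X <- Z %*% mixx + matrix(rnorm(N * d, 0, 1), N, d)
  Y <- Z %*% mixy + matrix(rnorm(N * d, 0, 1), N, d)
  gap <- vapply(c(0.05, 0.5), function(fr) {
    r <- train_probe(X, Y, "joint_single_W", train_frac = fr, steps = 500L,
                     seed = 84L)
    r$train_auroc - r$auroc
  }, numeric(1))
  expect_lt(gap[2], gap[1])
})

test_that("the conv probe has the printed architecture behavior", {
  set.seed(85)
  C <- 4L; L <- 9L
  stack <- array(runif(C * L * L), c(C, L, L))
  probe <- conv_probe(C, seed = 85L)
  # zero final layer: all probabilities 0.5
  probe0 <- probe
  probe0$c4$w[] <- 0; probe0$c4$b[] <- 0
  out <- conv_probe_forward(stack, probe0)
  expect_equal(out$prob, rep(0.5, L))
  # output length L for a range of L (same padding)
  for (LL in c(1L, 3L, 7L)) {
    st <- array(runif(C * LL * LL), c(C, LL, LL))
    expect_length(conv_probe_forward(st, probe)$prob, LL)
  }
  # permuting channels together with first-layer kernel blocks is a no-op
  perm <- sample(C)
  stack_p <- stack[perm, , , drop = FALSE]
  probe_p <- probe
  # first-layer weight rows are ordered offset-major, channel-minor
  for (off in 0:8) {
    rows <- off * C + seq_len(C)
    probe_p$c1$w[rows, ] <- probe$c1$w[rows[perm], ]
  }
  expect_equal(conv_probe_forward(stack_p, probe_p)$prob,
               conv_probe_forward(stack, probe)$prob, tolerance = 1e-10)
})

test_that("conv probe training gradients match finite differences", {
  set.seed(86)
  C <- 3L; L <- 6L
  stack <- array(runif(C * L * L), c(C, L, L))
  probe <- conv_probe(C, hidden = 5L, seed = 86L)
  labels <- sample(0:1, L, replace = TRUE)
  loss_of <- function(pr) {
    p <- conv_probe_forward(stack, pr)$prob
    -mean(labels * log(p) + (1 - labels) * log(1 - p))
  }
  fw <- conv_probe_forward(stack, probe, cache = TRUE)
  dlogit <- (fw$prob - labels) / L
  g <- momlm:::.conv_probe_bwd(dlogit, probe, fw$cache)
  eps <- 1e-6
  for (nm in c("c1", "c2", "c3", "c4")) {
    for (fld in c("w", "b")) {
      arr <- probe[[nm]][[fld]]
      for (i in sample(length(arr), min(3L, length(arr)))) {
        pp <- probe; pp[[nm]][[fld]][i] <- pp[[nm]][[fld]][i] + eps
        pm <- probe; pm[[nm]][[fld]][i] <- pm[[nm]][[fld]][i] - eps
        num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
        expect_equal(g[[paste0(nm, ".", fld)]][i], num, tolerance = 1e-4,
                     info = paste(nm, fld, i))
      }
    }
  }
})

test_that("probe training is seed-deterministic and flags all-negative labels", {
  set.seed(87)
  stacks <- lapply(1:8, function(i) array(runif(3 * 5 * 5), c(3, 5, 5)))
  labels <- lapply(1:8, function(i) sample(0:1, 5, replace = TRUE))
  r1 <- train_conv_probe(stacks, labels, steps = 30L, batch = 4L,
                         test_idx = 7:8, seed = 5L)
  r2 <- train_conv_probe(stacks, labels, steps = 30L, batch = 4L,
                         test_idx = 7:8, seed = 5L)
  expect_identical(r1$f1, r2$f1)
  neg <- lapply(labels, function(l) l * 0)
  expect_warning(train_conv_probe(stacks, neg, steps = 2L, batch = 2L,
                                  seed = 1L), "all-negative")
})

test_that("probes trained on two stack sources report per-fold F1 deltas", {
  set.seed(88)
  stacks_a <- lapply(1:10, function(i) array(runif(2 * 5 * 5), c(2, 5, 5)))
  stacks_b <- lapply(1:10, function(i) array(runif(2 * 5 * 5), c(2, 5, 5)))
  labels <- lapply(stacks_a, function(s) as.numeric(rowMeans(s[1, , ]) > 0.5))
  cmp <- compare_attention_probes(stacks_a, stacks_b, labels, n_folds = 2L,
                                  steps = 40L, batch = 4L, seed = 88L)
  expect_equal(nrow(cmp), 2L)
  expect_true(all(is.finite(cmp$delta)))
})
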
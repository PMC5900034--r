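# PCA, bi-cross-validated rank, MMC, leave-mouse-out CV

test_that("pca matches a covariance eigendecomposition", {
  set.seed(4)
  m <- matrix(rnorm(30 * 8), 30, 8)
  pc <- pca_fit(m)
  ev <- eigen(stats::cov(m), symmetric = TRUE)$values
  expl_oracle <- ev / sum(ev)
  expect_equal(pc$explained, expl_oracle[seq_len(pc$rank)], tolerance = 1e-10)
  # loadings orthonormal
  expect_equal(
    crossprod(pc$loadings), diag(pc$rank),
    tolerance = 1e-8, ignore_attr = TRUE
  )
  # full-rank reconstruction
  rec <- sweep(pc$scores %*% t(pc$loadings), 2, -pc$mean)
  expect_equal(rec, m, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("rank-1 data puts all variance on the first component", {
  u <- rnorm(20)
  v <- rnorm(6)
  m <- outer(u, v)
  pc <- pca_fit(m, rank = 3)
  expect_equal(pc$explained[1], 1, tolerance = 1e-10)
  # duplicated sample gets identical scores
  m2 <- rbind(m, m[1, ])
  pc2 <- pca_fit(m2, rank = 2)
  expect_equal(pc2$scores[1, ], pc2$scores[21, ], tolerance = 1e-10)
  expect_error(pca_fit(m, rank = 0), "rank")
})

test_that("bi-cross-validation finds an exact low rank", {
  set.seed(11)
  # exact rank-2 noiseless matrix
  m2 <- tcrossprod(matrix(rnorm(80), 40, 2), matrix(rnorm(60), 30, 2))
  k2 <- bcv_rank(m2, max_rank = 6, seed = 1)
  expect_equal(as.integer(k2), 2L)
  errs <- attr(k2, "errors")
  expect_lt(errs[["2"]], 1e-10)
})

test_that("bi-cross-validation returns 0 for structureless data", {
  set.seed(12)
  hits <- vapply(1:20, function(s) {
    m <- matrix(rnorm(40 * 60), 40, 60)
    as.integer(bcv_rank(m, max_rank = 4, seed = s))
  }, integer(1))
  expect_gte(mean(hits == 0L), 0.9)
})

test_that("mmc recovers the separating direction of two Gaussians", {
  set.seed(5)
  n <- 60
  x <- rbind(
    cbind(rnorm(n), rnorm(n)),
    cbind(rnorm(n, 10), rnorm(n))
  )
  lab <- rep(c("a", "b"), each = n)
  fit <- mmc(x, lab, n_components = 1)
  ang <- acos(abs(sum(fit$loadings[, 1] * c(1, 0))) /
    sqrt(sum(fit$loadings[, 1]^2))) * 180 / pi
  expect_lt(ang, 5)
  expect_error(mmc(x, rep("a", 2 * n)), "2 classes")
  expect_error(mmc(x[1:3, ], c("a", "a", "b")), "single sample")
})

test_that("mmc eigenpairs match a dense eigendecomposition", {
  m <- matrix(
    c(
      1.0, 2.0, 0.5, 1.5,
      1.2, 1.8, 0.7, 1.4,
      3.0, 0.5, 2.5, 0.2,
      2.8, 0.7, 2.2, 0.4,
      0.1, 3.1, 0.2, 2.9,
      0.3, 2.9, 0.1, 3.1
    ),
    nrow = 6, byrow = TRUE
  )
  lab <- c("a", "a", "b", "b", "c", "c")
  fit <- mmc(m, lab, n_components = 2)
  eg <- eigen(fit$S_b - fit$S_w, symmetric = TRUE)
  expect_equal(fit$eigenvalues, eg$values[1:2], tolerance = 1e-10)
  for (k in 1:2) {
    v <- eg$vectors[, k]
    w <- fit$loadings[, k]
    expect_equal(abs(sum(v * w)), 1, tolerance = 1e-8)
  }
  # scatter matrices are symmetric PSD (S_b at least)
  expect_equal(fit$S_b, t(fit$S_b), tolerance = 1e-12)
  expect_true(all(eigen(fit$S_b, symmetric = TRUE)$values > -1e-10))
})

test_that("mmc objective beats random orthonormal projections", {
  set.seed(6)
  m <- matrix(rnorm(40 * 6), 40, 6)
  lab <- rep(c("a", "b"), each = 20)
  m[lab == "b", 1] <- m[lab == "b", 1] + 2
  fit <- mmc(m, lab, n_components = 2)
  A <- fit$S_b - fit$S_w
  obj <- sum(diag(t(fit$loadings) %*% A %*% fit$loadings))
  rand_obj <- vapply(1:1000, function(i) {
    W <- qr.Q(qr(matrix(rnorm(6 * 2), 6, 2)))
    sum(diag(t(W) %*% A %*% W))
  }, numeric(1))
  expect_true(all(obj >= rand_obj - 1e-10))
})

test_that("leave-mouse-out CV is perfect on separable classes", {
  set.seed(7)
  n_mice <- 4
  reps <- 3
  mk <- function(cl, off) {
    t(sapply(seq_len(n_mice * reps), function(i) rnorm(5, off, 0.2)))
  }
  x <- rbind(mk("a", 0), mk("b", 10))
  lab <- rep(c("a", "b"), each = n_mice * reps)
  mouse <- paste0(lab, rep(rep(seq_len(n_mice), each = reps), 2))
  rep_cv <- leave_mouse_out_cv(x, lab, mouse, n_components = 1)
  expect_equal(rep_cv$accuracy, 1.0)
  expect_true(all(rep_cv$confusion[row(rep_cv$confusion) != col(rep_cv$confusion)] == 0))
  expect_gt(rep_cv$predicted_variance, 0.9)
})

test_that("no training fold contains spectra of its held-out mouse", {
  set.seed(8)
  x <- matrix(rnorm(24 * 4), 24, 4)
  lab <- rep(c("a", "b"), each = 12)
  mouse <- paste0(lab, rep(1:4, each = 3))
  # structural check via a selection step that records training mice
  seen <- new.env()
  seen$folds <- list()
  tr_ids <- leave_mouse_out_cv(x, lab, mouse, n_components = 1)
  asg <- tidy(tr_ids)
  expect_setequal(unique(asg$mouse_id), unique(mouse))
  expect_equal(nrow(asg), nrow(x))
  # each sample predicted exactly once, under its own mouse's fold
  expect_equal(sort(table(asg$mouse_id)), sort(table(mouse)),
    ignore_attr = TRUE
  )
})

test_that("null classes give chance-level accuracy across seeds", {
  accs <- vapply(1:30, function(s) {
    set.seed(100 + s)
    x <- matrix(rnorm(24 * 6), 24, 6)
    lab <- rep(c("a", "b"), each = 12)
    mouse <- paste0(lab, rep(1:4, each = 3))
    leave_mouse_out_cv(x, lab, mouse, n_components = 1)$accuracy
  }, numeric(1))
  # mean of run accuracies consistent with 0.5
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 1e-9)
})

test_that("label shuffling collapses a real signal to chance (leakage guard)", {
  set.seed(9)
  n_mice <- 6
  reps <- 2
  lab <- rep(c("a", "b"), each = n_mice * reps)
  mouse <- paste0(lab, rep(rep(seq_len(n_mice), each = reps), 2))
  x <- matrix(rnorm(length(lab) * 40), length(lab), 40)
  x[lab == "b", 1:5] <- x[lab == "b", 1:5] + 3
  real <- leave_mouse_out_cv(x, lab, mouse,
    select_features = TRUE, n_components = 1
  )
  expect_gt(real$accuracy, 0.9)
  sh_accs <- vapply(1:10, function(s) {
    set.seed(200 + s)
    perm_mice <- sample(unique(mouse))
    lab_of_mouse <- setNames(
      rep(c("a", "b"), length.out = length(perm_mice)), perm_mice
    )
    sl <- lab_of_mouse[mouse]
    leave_mouse_out_cv(x, sl, mouse,
      select_features = TRUE, n_components = 1
    )$accuracy
  }, numeric(1))
  n_pred <- length(lab) * 10
  expect_lt(abs(mean(sh_accs) - 0.5), 1.96 * sqrt(0.25 / n_pred) * 3)
})

test_that("the CV report is invariant to sample order", {
  set.seed(10)
  x <- matrix(rnorm(24 * 5), 24, 5)
  rownames(x) <- sprintf("s%02d", 1:24)
  lab <- rep(c("a", "b"), each = 12)
  mouse <- paste0(lab, rep(1:4, each = 3))
  r1 <- leave_mouse_out_cv(x, lab, mouse, n_components = 1)
  o <- sample(24)
  r2 <- leave_mouse_out_cv(x[o, ], lab[o], mouse[o], n_components = 1)
  expect_equal(r1$accuracy, r2$accuracy)
  expect_equal(r1$confusion, r2$confusion)
})
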
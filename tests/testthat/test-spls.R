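make_xy <- function(n = 60, p = 8, q = 2, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  B <- matrix(0, p, q)
  B[1:2, 1] <- c(1.5, -1)
  if (q > 1) B[3, 2] <- 2
  Y <- X %*% B + matrix(rnorm(n * q, sd = 0.3), n, q)
  colnames(Y) <- paste0("y", 1:q)
  list(X = X, Y = Y, B = B)
}

test_that("dense single-component PLS1 direction is proportional to X'y", {
  d <- make_xy(q = 1)
  f <- suppressWarnings(fit_spls(d$X, d$Y, eta = 0, K = 1))
  Xc <- scale(d$X, scale = FALSE)
  yc <- scale(d$Y, scale = TRUE)
  m <- drop(crossprod(Xc, yc))
  expect_equal(abs(cor(f$W[, 1], m)), 1, tolerance = 1e-10)
})

test_that("dense PLS at full rank converges to the least-squares fit", {
  set.seed(4)
  n <- 80; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  Y <- X %*% c(1, -2, 0.5, 0) + rnorm(n, sd = 0.2)
  f <- fit_spls(X, Y, eta = 0, K = p)
  Xc <- scale(X, scale = FALSE)
  ys <- scale(Y)
  b_ols <- solve(crossprod(Xc), crossprod(Xc, ys))
  expect_lt(max(abs(f$B - b_ols)) / max(abs(b_ols)), 1e-3)
})

test_that("duplicated predictors receive equal weights", {
  d <- make_xy()
  X <- cbind(d$X, dup = d$X[, 1])
  f <- suppressWarnings(fit_spls(X, d$Y, eta = 0.3, K = 3))
  expect_equal(f$W[1, ], f$W[ncol(X), ], tolerance = 1e-8)
  expect_equal(f$B[1, ], f$B[ncol(X), ], tolerance = 1e-8)
})

test_that("the fitted model satisfies its structural invariants", {
  d <- make_xy(n = 50, p = 12, q = 3, seed = 2)
  f <- suppressWarnings(fit_spls(d$X, d$Y, eta = 0.5, K = 5))
  ## score columns mutually orthogonal
  G <- crossprod(f$scores)
  expect_lt(max(abs(G[upper.tri(G)])) / max(diag(G)), 1e-6)
  ## nonzero rows of B lie inside the support
  expect_true(all(rowSums(abs(f$B)) == 0 | f$support))
  ## joint row permutation leaves B unchanged
  set.seed(9); perm <- sample(nrow(d$X))
  f2 <- suppressWarnings(fit_spls(d$X[perm, ], d$Y[perm, ], eta = 0.5, K = 5))
  expect_equal(f$B, f2$B, tolerance = 1e-10)
  ## eta outside [0,1) rejected; K above rank reduced with a warning
  expect_error(fit_spls(d$X, d$Y, eta = 1), "eta")
  expect_warning(fit_spls(d$X[, 1:3], d$Y, eta = 0, K = 7), "reduced")
})

test_that("high sparsity zeroes out pure-noise predictors", {
  set.seed(21)
  n <- 100
  signal <- matrix(rnorm(n * 3), n, 3)
  noise <- matrix(rnorm(n * 40), n, 40)
  X <- cbind(signal, noise)
  Y <- signal %*% c(2, -2, 1.5) + rnorm(n, sd = 0.3)
  f <- suppressWarnings(fit_spls(X, Y, eta = 0.9, K = 3))
  expect_gte(mean(!f$support[4:43]), 0.9)
  expect_true(any(f$support[1:3]))
})

test_that("StARS instability equals the brute-force subset loop", {
  d <- make_xy(n = 48, p = 10, q = 2, seed = 3)
  subjects <- rep(paste0("s", 1:12), each = 4)
  prof <- stars_select_eta(d$X, d$Y, subjects,
                           eta_grid = c(0.2, 0.5, 0.8), n_subsets = 12,
                           K = 3, seed = 5, keep_subsets = TRUE)
  ss <- prof$subset_supports
  for (j in seq_along(prof$eta_grid)) {
    for (o in seq_len(ncol(d$X))) {
      th <- 0
      for (b in seq_len(dim(ss)[3])) th <- th + ss[o, j, b]
      th <- th / dim(ss)[3]
      expect_equal(unname(prof$theta[o, j]), th)
      expect_equal(unname(prof$xi[o, j]), 2 * th * (1 - th))
    }
    expect_equal(prof$D[j], mean(prof$xi[, j]))
  }
  ## xi arithmetic at the boundary frequencies
  expect_equal(2 * 1 * (1 - 1), 0)
  expect_equal(2 * 0.5 * 0.5, 0.5)
  expect_true(all(prof$theta >= 0 & prof$theta <= 1))
  expect_true(all(prof$xi >= 0 & prof$xi <= 0.5))
  ## monotonized path is non-decreasing from the sparse end
  ord <- order(prof$eta_grid, decreasing = TRUE)
  expect_true(!is.unsorted(prof$D_monotone[ord]))
})

test_that("bootstrap significance obeys the add-one empirical-p rules", {
  d <- make_xy(n = 60, p = 6, q = 2, seed = 8)
  subjects <- rep(paste0("s", 1:15), each = 4)
  res <- bootstrap_significance(d$X, d$Y, support = 1:4, subjects,
                                B_boot = 25, B_null = 49, alpha = 0.01,
                                K = 3, seed = 2)
  a <- res$associations
  expect_equal(nrow(a), 4 * 2)
  expect_true(all(a$p >= 1 / 50 & a$p <= 1))
  expect_true(all(a$p[a$significant] <= 0.01))
  ## an observed statistic beyond every null draw gets p = 1/(B_null + 1)
  expect_equal(min(a$p), 1 / 50, tolerance = 1e-12)
  expect_error(bootstrap_significance(d$X, d$Y, support = integer(),
                                      subjects), "empty support")
})

test_that("planted associations reach significance at alpha = 0.01", {
  sim <- simulate_cohort(sim_config(seed = 77))
  clr <- clr_transform(filter_prevalence(sim$table))
  meta <- sim$meta
  Y <- as.matrix(meta[, c("Fat", "BMC", "Lean", "DMI", "Weight",
                          "Weight+1", "NAFLD")])
  dx <- within_subject_split(clr$values, meta$subject_id, meta$diet)
  dy <- within_subject_split(Y, meta$subject_id, meta$diet)
  truth <- sim$truth$assoc_otus
  sup <- which(colnames(dx$within) %in% truth)
  res <- bootstrap_significance(dx$within, dy$within, sup,
                                meta$subject_id, B_boot = 40, B_null = 199,
                                seed = 31)
  a <- res$associations
  tc <- sim$truth$true_coefficients[a$otu, ]
  planted <- abs(tc[cbind(seq_len(nrow(a)), match(a$phenotype, colnames(tc)))]) > 0
  ## planted (OTU, phenotype) pairs overwhelmingly reach p <= 0.01
  expect_gt(mean(a$p[planted] <= 0.01), 0.8)
  ## coefficient signs agree with the planted signs for significant pairs
  sig_planted <- planted & a$p <= 0.01
  tcv <- tc[cbind(seq_len(nrow(a)), match(a$phenotype, colnames(tc)))]
  expect_gt(mean(sign(a$coefficient[sig_planted]) ==
                   sign(tcv[sig_planted])), 0.9)
})
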
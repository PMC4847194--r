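#' Sparse partial least squares regression
#'
#' Fits a bi-linear PLS model in regression mode with an L1 penalty on the
#' X-direction vectors: per component the dominant left singular vector of
#' the current cross-covariance matrix is soft-thresholded at
#' \code{eta * max(|entry|)}, X is deflated by the resulting score, and the
#' coefficient matrix is assembled from the retained directions. With
#' \code{eta = 0} this reproduces dense PLS; as \code{eta} approaches 1 the
#' support shrinks to the single strongest variable per component. The
#' support of the model is per feature (OTU): any feature with a nonzero
#' weight in some component is in the support.
#'
#' X columns are centered internally; Y columns are centered and scaled
#' (responses enter on a common standardized scale). Coefficients in
#' \code{B} map centered X to standardized Y.
#'
#' @param X numeric matrix, samples x features (typically the within-subject
#'   clr component).
#' @param Y numeric matrix (or vector), samples x responses.
#' @param eta sparsity weight in [0, 1).
#' @param K number of latent components; default 7. Reduced with a warning
#'   if it exceeds the number of non-negligible singular values of the
#'   cross-covariance.
#' @return object of class \code{spls} with elements \code{W} (p x K
#'   X-weights), \code{scores} (n x K score matrix T), \code{C} (q x K
#'   response weights), \code{B} (p x q coefficients), \code{support}
#'   (logical p), \code{eta}, \code{K} (components actually fit), plus
#'   centering/scaling constants.
#' @export
fit_spls <- function(X, Y, eta, K = 7) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same rows")
  if (eta < 0 || eta >= 1) stop("eta must be in [0, 1)")
  p <- ncol(X); q <- ncol(Y); n <- nrow(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(p))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("Y", seq_len(q))
  x_center <- colMeans(X)
  y_center <- colMeans(Y)
  y_scale <- apply(Y, 2L, stats::sd)
  y_scale[y_scale == 0 | is.na(y_scale)] <- 1
  Xc <- sweep(X, 2L, x_center)
  Yc <- sweep(sweep(Y, 2L, y_center), 2L, y_scale, "/")
  K_req <- K
  K <- min(K, n - 1L, p)
  W <- matrix(0, p, K); Tm <- matrix(0, n, K)
  P <- matrix(0, p, K); C <- matrix(0, q, K)
  Xd <- Xc; Yd <- Yc
  tol <- 1e-12 * max(1, sum(abs(crossprod(Xc, Yc))))
  k <- 0L
  while (k < K) {
    M <- crossprod(Xd, Yd)                     # p x q cross-covariance
    sv <- svd(M, nu = 1L, nv = 1L)
    if (sv$d[1] <= tol) break                  # rank of cross-cov exhausted
    u <- sv$u[, 1L]
    thr <- eta * max(abs(u))
    w <- sign(u) * pmax(abs(u) - thr, 0)
    nw <- sqrt(sum(w^2))
    if (nw == 0) break
    w <- w / nw
    t_k <- drop(Xd %*% w)
    tt <- sum(t_k^2)
    if (tt <= 1e-300) break
    p_k <- drop(crossprod(Xd, t_k)) / tt
    c_k <- drop(crossprod(Yd, t_k)) / tt
    k <- k + 1L
    W[, k] <- w; Tm[, k] <- t_k; P[, k] <- p_k; C[, k] <- c_k
    Xd <- Xd - tcrossprod(t_k, p_k)
    Yd <- Yd - tcrossprod(t_k, c_k)
  }
  if (k < K_req)
    warning("number of components reduced to ", k,
            " (rank of cross-covariance)")
  if (k == 0L) stop("no informative component: cross-covariance is null")
  W <- W[, seq_len(k), drop = FALSE]; Tm <- Tm[, seq_len(k), drop = FALSE]
  P <- P[, seq_len(k), drop = FALSE]; C <- C[, seq_len(k), drop = FALSE]
  ## B = W (P'W)^{-1} C'
  B <- W %*% solve(crossprod(P, W), t(C))
  dimnames(B) <- list(colnames(X), colnames(Y))
  rownames(W) <- colnames(X); rownames(C) <- colnames(Y)
  support <- rowSums(abs(W)) > 0
  names(support) <- colnames(X)
  structure(list(W = W, scores = Tm, loadings = P, C = C, B = B,
                 support = support, eta = eta, K = k, K_requested = K_req,
                 x_center = x_center, y_center = y_center, y_scale = y_scale),
            class = "spls")
}

#' @export
print.spls <- function(x, ...) {
  cat(sprintf("sparse PLS model: %d features -> %d responses, K = %d, eta = %g\n",
              nrow(x$B), ncol(x$B), x$K, x$eta))
  cat(sprintf("  support: %d of %d features\n", sum(x$support),
              length(x$support)))
  invisible(x)
}

#' @export
coef.spls <- function(object, ...) object$B

#' @export
predict.spls <- function(object, newdata, ...) {
  Xc <- sweep(as.matrix(newdata), 2L, object$x_center)
  Yhat <- Xc %*% object$B
  sweep(sweep(Yhat, 2L, object$y_scale, "*"), 2L, object$y_center, "+")
}

#' StARS selection of the sPLS sparsity weight
#'
#' Rebuilds the sPLS model over random subject-level subsets of the data
#' across a grid of sparsity weights, records per-feature selection
#' frequencies theta, and summarizes instability per eta as the mean of
#' xi = 2 theta (1 - theta). Instability is monotonized by a running
#' maximum along the path from the sparsest (largest eta) to the densest
#' model; the selected eta is the least sparse one whose monotonized
#' instability stays at or below the variability threshold. Subsets are
#' drawn by subject so repeated measures of one subject never straddle a
#' subset boundary.
#'
#' @param X,Y data matrices as in [fit_spls].
#' @param subjects subject id per row; subsampling is by subject.
#' @param eta_grid sorted grid of sparsity weights; default 0.05..0.95.
#' @param n_subsets number of random subsets; default 50.
#' @param subsample_fraction fraction of subjects per subset; default
#'   \code{10 sqrt(S)/S} for S > 144 subjects, 0.8 otherwise (StARS
#'   convention).
#' @param threshold variability threshold on the instability scale;
#'   default 0.001 (i.e. 0.1\%).
#' @param K number of sPLS components; default 7.
#' @param seed integer seed.
#' @param keep_subsets also return the per-subset support indicators
#'   (features x etas x subsets); default FALSE.
#' @return object of class \code{stars_profile}: \code{eta_grid},
#'   \code{theta} (features x etas selection frequencies), \code{xi},
#'   \code{D} (mean instability per eta), \code{D_monotone},
#'   \code{eta_selected}, \code{support} (full-data refit at the selected
#'   eta), \code{threshold_met} flag, and the full-data \code{fit}.
#' @export
stars_select_eta <- function(X, Y, subjects,
                             eta_grid = seq(0.05, 0.95, by = 0.05),
                             n_subsets = 50, subsample_fraction = NULL,
                             threshold = 0.001, K = 7, seed = 1L,
                             keep_subsets = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.unsorted(eta_grid)) stop("eta_grid must be sorted increasing")
  subjects <- as.character(subjects)
  subj <- unique(subjects)
  S <- length(subj)
  if (is.null(subsample_fraction))
    ## StARS convention: b(S) = 10 sqrt(S) when that is a proper subset,
    ## 0.8 S for small cohorts (a full-data "subset" has zero instability)
    subsample_fraction <- if (S > 144) 10 * sqrt(S) / S else 0.8
  if (!(subsample_fraction > 0 && subsample_fraction <= 1))
    stop("subsample_fraction must be in (0, 1]")
  m <- max(2L, floor(subsample_fraction * S))
  p <- ncol(X); ne <- length(eta_grid)
  sel <- array(0L, dim = c(p, ne))
  subset_supports <- if (keep_subsets)
    array(FALSE, dim = c(p, ne, n_subsets)) else NULL
  restore <- local_rng(seed)
  on.exit(restore())
  for (b in seq_len(n_subsets)) {
    take <- sample(subj, m, replace = FALSE)
    rows <- subjects %in% take
    Xi <- X[rows, , drop = FALSE]; Yi <- Y[rows, , drop = FALSE]
    for (j in seq_len(ne)) {
      fit <- suppressWarnings(fit_spls(Xi, Yi, eta = eta_grid[j], K = K))
      sel[, j] <- sel[, j] + as.integer(fit$support)
      if (keep_subsets) subset_supports[, j, b] <- fit$support
    }
  }
  theta <- sel / n_subsets
  xi <- 2 * theta * (1 - theta)
  D <- colMeans(xi)
  ## path: sparsest (largest eta) first
  ord <- order(eta_grid, decreasing = TRUE)
  D_mono_path <- cummax(D[ord])
  D_monotone <- numeric(ne); D_monotone[ord] <- D_mono_path
  ok <- which(D_mono_path <= threshold)
  threshold_met <- length(ok) > 0
  if (threshold_met) {
    pick <- max(ok)                            # least sparse on the path
    ties <- ok[D_mono_path[ok] == D_mono_path[pick]]
    pick <- min(ties)                          # equal instability: sparser
    eta_selected <- eta_grid[ord[pick]]
  } else {
    ## nothing on the path is stable enough: keep the most stable end of
    ## the path (the sparsest model), flagged via threshold_met
    eta_selected <- max(eta_grid)
  }
  fit <- suppressWarnings(fit_spls(X, Y, eta = eta_selected, K = K))
  rownames(theta) <- rownames(xi) <- rownames(fit$B)
  structure(list(eta_grid = eta_grid, theta = theta, xi = xi, D = D,
                 D_monotone = D_monotone, eta_selected = eta_selected,
                 threshold = threshold, threshold_met = threshold_met,
                 n_subsets = n_subsets,
                 subsample_fraction = subsample_fraction,
                 support = fit$support, fit = fit,
                 subset_supports = subset_supports),
            class = "stars_profile")
}

#' @export
print.stars_profile <- function(x, ...) {
  cat(sprintf(
    "StARS profile: %d etas x %d subsets; selected eta = %g (%s), support %d\n",
    length(x$eta_grid), x$n_subsets, x$eta_selected,
    if (x$threshold_met) "threshold met" else "threshold NOT met",
    sum(x$support)))
  invisible(x)
}

#' Bootstrap and permutation significance of sPLS associations
#'
#' Restricted to the StARS-selected support, refits dense PLS models over
#' subject-level bootstrap resamples to obtain a coefficient estimate per
#' (feature, response) pair (the median over bootstraps, or the original
#' fit), and builds an empirical null by refitting after randomly permuting
#' the subject-to-response assignment. Two-sided empirical p-values use the
#' add-one rule, p = (1 + #{|null| >= |observed|}) / (1 + n_null), so p is
#' never zero.
#'
#' @param X,Y data matrices as in [fit_spls].
#' @param support logical vector over columns of X (from [stars_select_eta]).
#' @param subjects subject id per row; resampling and permutation are at
#'   subject level.
#' @param B_boot number of bootstrap refits; default 2000.
#' @param B_null number of permutation refits; default \code{B_boot}.
#' @param alpha significance level; default 0.01.
#' @param K components for the restricted refits; default 7.
#' @param statistic \code{"median"} (bootstrap median coefficient, default)
#'   or \code{"original"} (full-data fit coefficient).
#' @param seed integer seed.
#' @return object of class \code{association_result}: a data.frame with one
#'   row per (feature, response) pair in the support, columns
#'   \code{otu}, \code{phenotype}, \code{coefficient}, \code{p},
#'   \code{significant}.
#' @export
bootstrap_significance <- function(X, Y, support, subjects, B_boot = 2000,
                                   B_null = B_boot, alpha = 0.01, K = 7,
                                   statistic = c("median", "original"),
                                   seed = 1L) {
  statistic <- match.arg(statistic)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.logical(support)) support <- which(support)
  if (length(support) == 0L) stop("empty support: nothing to test")
  Xs <- X[, support, drop = FALSE]
  subjects <- as.character(subjects)
  subj <- unique(subjects)
  rows_of <- split(seq_along(subjects), subjects)[subj]
  q <- ncol(Y); s <- ncol(Xs)
  Kr <- min(K, s)
  refit <- function(rows, Ymat) {
    f <- suppressWarnings(fit_spls(Xs[rows, , drop = FALSE],
                                   Ymat[rows, , drop = FALSE],
                                   eta = 0, K = Kr))
    f$B
  }
  restore <- local_rng(seed)
  on.exit(restore())
  obs_fit <- refit(seq_len(nrow(Xs)), Y)
  boot <- array(NA_real_, dim = c(s, q, B_boot))
  for (b in seq_len(B_boot)) {
    pick <- sample(subj, length(subj), replace = TRUE)
    rows <- unlist(rows_of[pick], use.names = FALSE)
    boot[, , b] <- refit(rows, Y)
  }
  est <- if (statistic == "median") apply(boot, c(1, 2), stats::median)
         else obs_fit
  ## null: permute which subject's responses go with which subject's features
  sizes <- lengths(rows_of)
  balanced <- length(unique(sizes)) == 1L
  nullmat <- array(NA_real_, dim = c(s, q, B_null))
  all_rows <- seq_len(nrow(Xs))
  for (b in seq_len(B_null)) {
    if (balanced) {
      perm <- sample(seq_along(subj))
      yrows <- unlist(rows_of[perm], use.names = FALSE)
      xrows <- unlist(rows_of, use.names = FALSE)
      Yp <- Y
      Yp[xrows, ] <- Y[yrows, , drop = FALSE]
    } else {
      Yp <- Y[sample(all_rows), , drop = FALSE]
    }
    nullmat[, , b] <- refit(all_rows, Yp)
  }
  pmat <- matrix(NA_real_, s, q)
  for (i in seq_len(s)) for (j in seq_len(q))
    pmat[i, j] <- (1 + sum(abs(nullmat[i, j, ]) >= abs(est[i, j]))) /
      (1 + B_null)
  res <- data.frame(
    otu = rep(colnames(Xs), q),
    phenotype = rep(colnames(Y), each = s),
    coefficient = as.vector(est),
    p = as.vector(pmat),
    significant = as.vector(pmat) <= alpha,
    stringsAsFactors = FALSE)
  structure(list(associations = res, alpha = alpha, B_boot = B_boot,
                 B_null = B_null, statistic = statistic),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "association_result: %d pairs tested, %d significant at alpha = %g\n",
    nrow(x$associations), sum(x$associations$significant), x$alpha))
  invisible(x)
}
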
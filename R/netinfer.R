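#' Construct an association network
#'
#' Signed undirected OTU graph: node ids with optional phylum labels, and
#' an edge table with sign, weight and StARS selection frequency.
#'
#' @param nodes character vector of node (OTU) ids.
#' @param edges data.frame with columns \code{otu_a}, \code{otu_b},
#'   \code{sign} (+1/-1), \code{weight} (>= 0), \code{stars_frequency}.
#' @param phylum optional phylum label per node (named or positional).
#' @param lambda_selected optional selected penalty.
#' @param threshold_met logical; FALSE when StARS never reached its
#'   variability threshold and the sparsest graph was returned.
#' @export
association_network <- function(nodes, edges = NULL, phylum = NULL,
                                lambda_selected = NA_real_,
                                threshold_met = TRUE) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node ids")
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(otu_a = character(), otu_b = character(),
                        sign = numeric(), weight = numeric(),
                        stars_frequency = numeric())
  } else {
    edges <- as.data.frame(edges)
    need <- c("otu_a", "otu_b", "sign", "weight", "stars_frequency")
    miss <- setdiff(need, names(edges))
    if ("stars_frequency" %in% miss) edges$stars_frequency <- NA_real_
    miss <- setdiff(need, names(edges))
    if (length(miss)) stop("edges lacks columns: ", paste(miss, collapse = ", "))
    if (any(edges$otu_a == edges$otu_b)) stop("self-edges are not allowed")
    if (!all(c(edges$otu_a, edges$otu_b) %in% nodes))
      stop("edge endpoints must be nodes")
    ## canonical order, no duplicate pairs
    swap <- edges$otu_a > edges$otu_b
    tmp <- edges$otu_a[swap]
    edges$otu_a[swap] <- edges$otu_b[swap]; edges$otu_b[swap] <- tmp
    if (anyDuplicated(paste(edges$otu_a, edges$otu_b)))
      stop("duplicate edges")
  }
  if (!is.null(phylum)) {
    if (is.null(names(phylum))) names(phylum) <- nodes
    phylum <- phylum[nodes]
  }
  structure(list(nodes = nodes, edges = edges, phylum = phylum,
                 lambda_selected = lambda_selected,
                 threshold_met = threshold_met),
            class = "association_network")
}

#' @export
print.association_network <- function(x, ...) {
  cat(sprintf("association_network: %d nodes, %d edges (%d +, %d -)%s\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$sign > 0),
              sum(x$edges$sign < 0),
              if (is.na(x$lambda_selected)) ""
              else sprintf(", lambda = %.4g", x$lambda_selected)))
  invisible(x)
}

#' Convert an association network to an igraph graph
#'
#' @param net an [association_network]
#' @return an undirected \pkg{igraph} graph with vertex attribute
#'   \code{phylum} and edge attributes \code{sign}, \code{weight},
#'   \code{stars_frequency}.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "association_network"))
  g <- igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = data.frame(name = net$nodes,
                          phylum = if (is.null(net$phylum)) "unknown"
                                   else unname(net$phylum)))
  g
}

#' Neighborhood-selection association graph at a fixed penalty
#'
#' Meinshausen-Buhlmann style: each clr-transformed, column-standardized
#' feature is regressed on all others with an L1 penalty; an edge is drawn
#' between i and j if either nodewise regression gives the other a nonzero
#' coefficient (OR rule), with the sign of the larger-magnitude coefficient.
#'
#' @param X numeric matrix, samples x features (clr values).
#' @param lambda penalty (> 0) on the standardized scale.
#' @param standardize standardize columns first (default TRUE).
#' @return signed weighted adjacency matrix (features x features); entry
#'   (i, j) is sign * max(|beta_ij|, |beta_ji|), zero when no edge.
#' @export
mb_neighborhood <- function(X, lambda, standardize = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (lambda <= 0 && p > n)
    stop("lambda = 0 with p > n is unidentifiable")
  if (standardize) X <- scale(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))
  Bhat <- matrix(0, p, p, dimnames = list(colnames(X), colnames(X)))
  for (j in seq_len(p)) {
    fit <- glmnet::glmnet(X[, -j, drop = FALSE], X[, j],
                          lambda = lambda, standardize = FALSE)
    Bhat[j, -j] <- as.vector(fit$beta)
  }
  adj <- matrix(0, p, p, dimnames = dimnames(Bhat))
  for (i in seq_len(p - 1L)) for (j in seq.int(i + 1L, p)) {
    a <- Bhat[i, j]; b <- Bhat[j, i]
    if (a != 0 || b != 0) {
      v <- if (abs(a) >= abs(b)) a else b
      adj[i, j] <- adj[j, i] <- v
    }
  }
  adj
}

## nodewise lasso support over a whole lambda path, for StARS subsampling
mb_support_path <- function(X, lambda_grid) {
  p <- ncol(X); nl <- length(lambda_grid)
  out <- array(FALSE, dim = c(p, p, nl))
  for (j in seq_len(p)) {
    fit <- glmnet::glmnet(X[, -j, drop = FALSE], X[, j],
                          lambda = lambda_grid, standardize = FALSE)
    bj <- as.matrix(fit$beta) != 0                  # (p-1) x nl'
    nl_fit <- ncol(bj)
    idx <- seq_len(p)[-j]
    for (l in seq_len(nl)) {
      ll <- min(l, nl_fit)                          # glmnet may stop early
      out[j, idx, l] <- out[j, idx, l] | bj[, ll]
      out[idx, j, l] <- out[idx, j, l] | bj[, ll]   # OR symmetrization
    }
  }
  out
}

#' StARS-selected microbial association network
#'
#' Runs nodewise-lasso neighborhood selection over random subsamples and a
#' decreasing log-spaced penalty grid, computes per-edge selection
#' frequencies theta and the mean edge instability 2 theta (1 - theta),
#' monotonizes the instability along the path from sparsest to densest,
#' and returns the densest graph whose monotonized instability stays at or
#' below the variability threshold, refit on the full data.
#'
#' @param X numeric matrix, samples x features (clr values; standardized
#'   internally).
#' @param lambda_grid decreasing penalty grid; default 30 log-spaced points
#'   from lambda_max (largest absolute off-diagonal correlation) down to
#'   lambda_max / 100.
#' @param n_subsets number of random subsamples; default 50.
#' @param threshold variability threshold; default 0.0005 (0.05\%). The
#'   conventional StARS default 0.05 can be supplied instead.
#' @param subsample_size rows per subsample; default
#'   \code{min(n - 1, ceiling(10 sqrt(n)))}.
#' @param phylum optional phylum labels for the features.
#' @param seed integer seed.
#' @return an [association_network] with per-edge \code{stars_frequency}
#'   and the selected penalty; \code{threshold_met = FALSE} (sparsest graph
#'   returned) when no penalty meets the threshold.
#' @export
stars_network <- function(X, lambda_grid = NULL, n_subsets = 50,
                          threshold = 0.0005, subsample_size = NULL,
                          phylum = NULL, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))
  Xs <- scale(X)
  Xs[is.na(Xs)] <- 0                       # constant columns
  if (is.null(lambda_grid)) {
    cc <- stats::cor(Xs)
    cc[is.na(cc)] <- 0
    lmax <- max(abs(cc[upper.tri(cc)]))
    if (lmax <= 0) lmax <- 1
    lambda_grid <- exp(seq(log(lmax), log(lmax / 100), length.out = 30))
  }
  if (is.unsorted(rev(lambda_grid))) stop("lambda_grid must be decreasing")
  if (is.null(subsample_size))
    subsample_size <- min(n - 1L, ceiling(10 * sqrt(n)))
  nl <- length(lambda_grid)
  freq <- array(0L, dim = c(p, p, nl))
  restore <- local_rng(seed)
  on.exit(restore())
  for (b in seq_len(n_subsets)) {
    rows <- sample(n, subsample_size, replace = FALSE)
    Xi <- scale(X[rows, , drop = FALSE])
    Xi[is.na(Xi)] <- 0
    freq <- freq + mb_support_path(Xi, lambda_grid)
  }
  theta <- freq / n_subsets
  ut <- upper.tri(theta[, , 1L])
  D <- apply(theta, 3L, function(th) mean(2 * th[ut] * (1 - th[ut])))
  D_monotone <- cummax(D)                  # grid runs sparsest -> densest
  ok <- which(D_monotone <= threshold)
  threshold_met <- length(ok) > 0
  idx <- if (threshold_met) max(ok) else 1L
  lambda_sel <- lambda_grid[idx]
  adj <- mb_neighborhood(Xs, lambda_sel, standardize = FALSE)
  th_sel <- theta[, , idx]
  edges <- NULL
  pairs <- which(upper.tri(adj) & adj != 0, arr.ind = TRUE)
  if (nrow(pairs)) {
    edges <- data.frame(
      otu_a = colnames(X)[pairs[, 1L]],
      otu_b = colnames(X)[pairs[, 2L]],
      sign = sign(adj[pairs]),
      weight = abs(adj[pairs]),
      stars_frequency = th_sel[pairs])
  }
  net <- association_network(colnames(X), edges, phylum = phylum,
                             lambda_selected = lambda_sel,
                             threshold_met = threshold_met)
  net$lambda_grid <- lambda_grid
  net$instability <- D
  net$instability_monotone <- D_monotone
  net
}
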
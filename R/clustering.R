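#' Gaussian-mixture clustering of sPLS sample scores
#'
#' Fits finite Gaussian mixture models by EM over a range of cluster counts
#' and covariance families, initialized from model-based agglomerative
#' hierarchical clustering, and keeps the fit maximizing BIC
#' (2 loglik - npar log n). Computation is delegated to \pkg{mclust}.
#'
#' @param scores numeric matrix, samples x latent dimensions (e.g. the
#'   score matrix of a [fit_spls] model).
#' @param k_range candidate cluster counts; default 1:9.
#' @param families mclust covariance family codes. The default spans
#'   spherical (EII, VII), diagonal (EEI, VVI), tied-full (EEE),
#'   ellipsoidal equal-orientation (VVE) and full (VVV) models.
#' @param seed integer seed (EM for some families uses random restarts).
#' @importFrom mclust Mclust mclustBIC
#' @return object of class \code{gmm_fit}: \code{k}, \code{model_family},
#'   \code{means} (dims x k), \code{assignment}, \code{responsibilities},
#'   \code{bic_table} (k x family), \code{loglik}, and the underlying
#'   \code{mclust} fit.
#' @export
cluster_scores <- function(scores, k_range = 1:9,
                           families = c("EII", "VII", "EEI", "VVI",
                                        "EEE", "VVE", "VVV"),
                           seed = 1L) {
  scores <- as.matrix(scores)
  if (any(!is.finite(scores))) stop("scores must be finite")
  k_range <- k_range[k_range < nrow(scores)]
  if (!length(k_range)) stop("all k in k_range exceed the sample count")
  restore <- local_rng(seed)
  on.exit(restore())
  bic <- mclust::mclustBIC(scores, G = k_range, modelNames = families,
                           verbose = FALSE)
  fit <- mclust::Mclust(scores, x = bic, verbose = FALSE)
  if (is.null(fit)) stop("no mixture model could be fit")
  structure(list(k = fit$G, model_family = fit$modelName,
                 means = fit$parameters$mean,
                 covariances = fit$parameters$variance,
                 assignment = fit$classification,
                 responsibilities = fit$z,
                 bic_table = apply(fit$BIC, c(1, 2), identity),
                 loglik = fit$loglik,
                 mclust = fit),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("gmm_fit: %d clusters, family %s, loglik %.2f\n",
              x$k, x$model_family, x$loglik))
  cat("cluster sizes:", table(x$assignment), "\n")
  invisible(x)
}

#' Cluster-transition diagram
#'
#' Tallies cluster moves between successive available sampling weeks per
#' subject. Between-cluster edges observed fewer than \code{min_count}
#' times are dropped; self-loops (no change) are retained and reported
#' separately.
#'
#' @param assignments cluster label per sample.
#' @param subjects subject id per sample.
#' @param weeks sampling week per sample; transitions are taken between
#'   successive available weeks regardless of spacing.
#' @param min_count minimum number of observed mouse cluster changes for a
#'   between-cluster edge to be kept; default 6.
#' @return list with \code{edges} (data.frame from, to, count — filtered),
#'   \code{self_loops} (data.frame cluster, count), and \code{all_moves}
#'   (unfiltered tally).
#' @export
transition_diagram <- function(assignments, subjects, weeks, min_count = 6) {
  n <- length(assignments)
  if (length(subjects) != n || length(weeks) != n)
    stop("assignments, subjects, weeks must be aligned")
  if (anyDuplicated(paste(subjects, weeks)))
    stop("one assignment per (subject, week) required")
  df <- data.frame(subject = as.character(subjects),
                   week = as.numeric(weeks),
                   cluster = assignments)
  df <- df[order(df$subject, df$week), ]
  from <- to <- c()
  for (s in unique(df$subject)) {
    cl <- df$cluster[df$subject == s]
    if (length(cl) > 1L) {
      from <- c(from, cl[-length(cl)])
      to <- c(to, cl[-1L])
    }
  }
  tab <- as.data.frame(table(from = from, to = to), stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, ]
  names(tab)[3] <- "count"
  loops <- tab[tab$from == tab$to, c("from", "count")]
  names(loops)[1] <- "cluster"
  moves <- tab[tab$from != tab$to, ]
  edges <- moves[moves$count >= min_count, ]
  rownames(edges) <- rownames(loops) <- NULL
  list(edges = edges, self_loops = loops, all_moves = tab,
       min_count = min_count)
}
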
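#' Prevalence filter
#'
#' Discards OTUs present (count > 0) in fewer than \code{min_fraction} of all
#' samples. The boundary is read strictly: an OTU present in exactly
#' \code{min_fraction} of samples is retained.
#'
#' @param table an [otu_table]
#' @param min_fraction minimum presence fraction in (0, 1]; default 0.10.
#' @return the filtered [otu_table]; the sample set is unchanged.
#' @export
filter_prevalence <- function(table, min_fraction = 0.10) {
  stopifnot(inherits(table, "otu_table"))
  if (!(min_fraction > 0 && min_fraction <= 1))
    stop("min_fraction must be in (0, 1]")
  presence <- colMeans(table$counts > 0)
  keep <- presence >= min_fraction
  if (!any(keep))
    stop("no OTU passes the prevalence filter; lower min_fraction")
  table[, keep]
}

#' Centered log-ratio transform
#'
#' Adds a pseudocount to every raw count and maps each sample to
#' clr_ij = ln(c_ij + pc) - mean_j ln(c_ij + pc), so each transformed row
#' sums to zero.
#'
#' @param table an [otu_table] (or a non-negative samples x OTUs matrix)
#' @param pseudocount positive value added to all counts; default 1.
#' @return object of class \code{clr_matrix}: list with \code{values}
#'   (samples x OTUs real matrix), \code{otu_ids}, \code{pseudocount}.
#' @export
clr_transform <- function(table, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  counts <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  lg <- log(counts + pseudocount)
  vals <- lg - rowMeans(lg)
  structure(list(values = vals, otu_ids = colnames(counts),
                 pseudocount = pseudocount),
            class = "clr_matrix")
}

#' @export
print.clr_matrix <- function(x, ...) {
  cat(sprintf("clr_matrix: %d samples x %d OTUs (pseudocount %g)\n",
              nrow(x$values), ncol(x$values), x$pseudocount))
  invisible(x)
}

#' Rarefy samples to even depth
#'
#' Subsamples each sample's observations without replacement (multivariate
#' hypergeometric) to exactly \code{depth} counts. Samples with fewer than
#' \code{depth} total counts are dropped, with a message listing them.
#'
#' @param table an [otu_table]
#' @param depth target per-sample count total; default 1000.
#' @param seed integer seed making the subsample reproducible.
#' @return a rarefied [otu_table]
#' @export
rarefy <- function(table, depth = 1000, seed = 1L) {
  stopifnot(inherits(table, "otu_table"), depth >= 1)
  totals <- rowSums(table$counts)
  keep <- totals >= depth
  if (!any(keep)) stop("all samples are below the rarefaction depth")
  if (any(!keep))
    message("dropped below-depth samples: ",
            paste(sample_ids(table)[!keep], collapse = ", "))
  counts <- table$counts[keep, , drop = FALSE]
  p <- ncol(counts)
  out <- counts
  rng <- local_rng(seed)
  for (i in seq_len(nrow(counts))) {
    ci <- counts[i, ]
    if (sum(ci) == depth) next
    pool <- rep.int(seq_len(p), ci)
    take <- sample(pool, depth, replace = FALSE)
    out[i, ] <- tabulate(take, nbins = p)
  }
  rng()
  otu_table(out, table$taxonomy)
}

## Run code under a private RNG state, restoring the caller's on exit.
## Returns the restore function; call it when done.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
    invisible(NULL)
  }
}
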
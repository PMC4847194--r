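#' Construct an OTU count table
#'
#' The universal carrier between pipeline stages: a non-negative integer
#' count matrix with samples as rows and OTUs as columns, plus optional
#' per-OTU taxonomy lineage strings (\code{k__...;p__...;...}).
#'
#' @param counts non-negative integer matrix, samples x OTUs. Row names are
#'   sample ids, column names OTU ids; both must be unique.
#' @param taxonomy optional character vector of lineage strings, one per OTU.
#' @return an object of class \code{otu_table}.
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop("counts must be a finite numeric matrix")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("OTU", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate OTU ids")
  if (!is.null(taxonomy)) {
    taxonomy <- as.character(taxonomy)
    if (length(taxonomy) != ncol(counts))
      stop("taxonomy length must equal number of OTUs")
    names(taxonomy) <- colnames(counts)
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs (total count %.0f)%s\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts),
              if (is.null(x$taxonomy)) "" else ", with taxonomy"))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

sample_ids <- function(x) rownames(x$counts)
otu_ids <- function(x) colnames(x$counts)

#' Subset an OTU table
#'
#' @param x an \code{otu_table}
#' @param i sample index (rows)
#' @param j OTU index (columns)
#' @param ... ignored
#' @export
`[.otu_table` <- function(x, i, j, ...) {
  cnt <- x$counts[i, j, drop = FALSE]
  tax <- if (is.null(x$taxonomy)) NULL else x$taxonomy[colnames(cnt)]
  otu_table(cnt, tax)
}

#' Extract the phylum from a taxonomy lineage string
#'
#' @param lineage character vector of semicolon-separated lineage strings
#'   with rank prefixes (\code{p__} marks the phylum).
#' @return character vector of phylum names; \code{"unknown"} where absent.
#' @export
phylum_of <- function(lineage) {
  out <- rep("unknown", length(lineage))
  m <- regmatches(lineage, regexpr("p__[^;]*", lineage))
  hit <- grepl("p__", lineage)
  out[hit] <- sub("^p__", "", m)
  out[out == ""] <- "unknown"
  out
}
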
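## Readers/writers for the standard interchange formats.
## File convention follows amplicon tooling: OTUs are stored as rows
## ("#OTU ID" header token), in-memory matrices are samples x OTUs.

#' Read an OTU count table
#'
#' Supports plain TSV (OTUs as rows, header row of sample ids beginning with
#' the \code{#OTU ID} token, optional trailing \code{taxonomy} column) and
#' BIOM 1.0 JSON (sparse or dense).
#'
#' @param path path to the file.
#' @param format \code{"tsv"} or \code{"biom-json"}.
#' @return an [otu_table].
#' @export
read_otu_table <- function(path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom-json") return(read_biom_json(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty OTU table file: ", path)
  ## header is the '#OTU ID' line; other leading '#' lines are comments
  hdr_i <- grep("^#OTU ID", lines)
  if (length(hdr_i) == 0L) {
    hdr_i <- which(!startsWith(lines, "#"))[1] - 1L
    if (is.na(hdr_i) || hdr_i < 1L) stop("no header row found in ", path)
  } else hdr_i <- hdr_i[1]
  header <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  body <- lines[-seq_len(hdr_i)]
  body <- body[!startsWith(body, "#")]
  if (length(body) == 0L) stop("OTU table has no data rows: ", path)
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(header)))
    stop("ragged row at line ", hdr_i + which(nf != length(header))[1],
         " of ", path)
  has_tax <- tolower(header[length(header)]) %in% c("taxonomy", "consensus lineage")
  samp <- header[-c(1L, if (has_tax) length(header))]
  mat <- do.call(rbind, parts)
  otus <- mat[, 1L]
  tax <- if (has_tax) mat[, ncol(mat)] else NULL
  num <- mat[, seq.int(2L, 1L + length(samp)), drop = FALSE]
  suppressWarnings(storage <- as.numeric(num))
  if (any(is.na(storage))) {
    bad <- which(is.na(matrix(storage, nrow = nrow(num))), arr.ind = TRUE)[1, 1]
    stop("non-numeric count at data line ", bad, " of ", path)
  }
  counts <- matrix(storage, nrow = nrow(num), dimnames = list(otus, samp))
  if (any(counts < 0)) stop("negative count in ", path)
  otu_table(t(counts), taxonomy = tax)
}

read_biom_json <- function(path) {
  if (requireNamespace("biomformat", quietly = TRUE)) {
    b <- biomformat::read_biom(path)
    counts <- as(biomformat::biom_data(b), "matrix")   # OTUs x samples
    tax <- tryCatch({
      om <- biomformat::observation_metadata(b)
      if (is.null(om)) NULL
      else if (is.data.frame(om)) apply(om, 1L, paste, collapse = ";")
      else vapply(om, function(r) paste(unlist(r), collapse = ";"),
                  character(1))
    }, error = function(e) NULL)
    if (!is.null(tax) && all(!nzchar(gsub(";", "", tax)))) tax <- NULL
    return(otu_table(t(counts), taxonomy = tax))
  }
  ## minimal BIOM 1.0 JSON fallback
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  otus <- vapply(j$rows, function(r) r$id, character(1))
  samp <- vapply(j$columns, function(s) s$id, character(1))
  counts <- matrix(0, length(otus), length(samp), dimnames = list(otus, samp))
  if (identical(j$matrix_type, "dense")) {
    for (i in seq_along(j$data)) counts[i, ] <- unlist(j$data[[i]])
  } else {
    for (trip in j$data)
      counts[trip[[1]] + 1L, trip[[2]] + 1L] <- trip[[3]]
  }
  tax <- vapply(j$rows, function(r) {
    tx <- r$metadata$taxonomy
    if (is.null(tx)) NA_character_ else paste(unlist(tx), collapse = ";")
  }, character(1))
  if (all(is.na(tax))) tax <- NULL
  otu_table(t(counts), taxonomy = tax)
}

#' Write an OTU table as TSV
#'
#' @param table an [otu_table]
#' @param path output path
#' @export
write_otu_table <- function(table, path) {
  counts <- t(table$counts)          # OTUs as rows on disk
  header <- c("#OTU ID", colnames(counts))
  rows <- cbind(rownames(counts),
                matrix(format(counts, scientific = FALSE, trim = TRUE),
                       nrow = nrow(counts)))
  if (!is.null(table$taxonomy)) {
    header <- c(header, "taxonomy")
    rows <- cbind(rows, table$taxonomy[rownames(counts)])
  }
  writeLines(c(paste(header, collapse = "\t"),
               apply(rows, 1L, paste, collapse = "\t")), path)
  invisible(path)
}

#' Read per-sample metadata
#'
#' TSV keyed by sample id, with columns \code{subject_id}, \code{week},
#' \code{treatment} (control/STAT), \code{diet} (NC/HFD), \code{sex} (M/F)
#' and any phenotype columns; unknown columns are preserved.
#'
#' @param path path to the metadata TSV.
#' @param table optional [otu_table]; sample ids absent from it trigger a
#'   warning listing them.
#' @return a \code{data.frame}, one row per sample, row names = sample ids.
#' @export
read_metadata <- function(path, table = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ## read everything as character first: sex "F" must not become logical
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "",
                          colClasses = "character")
  keep_chr <- c("sample_id", "subject_id", "treatment", "diet", "sex")
  for (cn in setdiff(names(df), keep_chr))
    df[[cn]] <- utils::type.convert(df[[cn]], as.is = TRUE)
  id_col <- if ("sample_id" %in% names(df)) "sample_id" else names(df)[1]
  if (anyDuplicated(df[[id_col]])) stop("duplicate sample ids in ", path)
  rownames(df) <- df[[id_col]]
  if ("treatment" %in% names(df) &&
      !all(df$treatment %in% c("control", "STAT")))
    stop("treatment must be 'control' or 'STAT'")
  if ("diet" %in% names(df) && !all(df$diet %in% c("NC", "HFD")))
    stop("diet must be 'NC' or 'HFD'")
  if ("sex" %in% names(df) && !all(df$sex %in% c("M", "F")))
    stop("sex must be 'M' or 'F'")
  if (!is.null(table)) {
    missing <- setdiff(rownames(df), sample_ids(table))
    if (length(missing))
      warning("metadata samples absent from OTU table: ",
              paste(missing, collapse = ", "))
  }
  df
}

#' Write per-sample metadata as TSV
#'
#' @param meta data.frame as returned by [read_metadata]
#' @param path output path
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an association network
#'
#' @param net an [association_network]
#' @param path output path
#' @param format \code{"edge_tsv"} (columns otu_a, otu_b, sign, weight,
#'   stars_frequency) or \code{"graphml"} (nodes carry a phylum attribute).
#' @export
write_network <- function(net, path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "association_network"))
  if (format == "edge_tsv") {
    e <- net$edges
    out <- data.frame(otu_a = e$otu_a, otu_b = e$otu_b, sign = e$sign,
                      weight = e$weight, stars_frequency = e$stars_frequency)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read an association network from edge TSV
#'
#' @param path edge TSV written by [write_network]
#' @param nodes optional full node id vector (isolated nodes are not
#'   recoverable from the edge list alone)
#' @param phylum optional named phylum vector for the nodes
#' @export
read_network <- function(path, nodes = NULL, phylum = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- sort(unique(c(df$otu_a, df$otu_b)))
  association_network(nodes = nodes, edges = df, phylum = phylum)
}
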
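#' Read a spectral-count table
#'
#' TSV with columns `protein_id`, one or more integer experiment count
#' columns, `crapome_frequency` (proportion of contaminant-catalogue
#' runs the protein appears in, in \[0, 1\]) and `is_ribosomal`
#' (TRUE/FALSE). The ribosomal flag is expected to come from a curated
#' id list rather than name pattern matching.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_spectral_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("protein_id", "crapome_frequency", "is_ribosomal")
  miss <- base::setdiff(req, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df$is_ribosomal <- as.logical(df$is_ribosomal)
  df
}

#' Filter chromatin interactors from replicate spectral counts
#'
#' The interactor-filtering rule for RIME-style proteomics: remove
#' proteins found in more than `crapome_max` of contaminant-catalogue
#' samples, ribosomal proteins, and proteins with a zero spectral count
#' in any experiment; then keep proteins whose mean count across
#' experiments is strictly greater than `min_avg`. Output is sorted by
#' mean count descending, ties broken by `protein_id`.
#'
#' The filter is monotone: raising `min_avg` or lowering `crapome_max`
#' never adds a protein.
#'
#' @param table Data frame with `protein_id`, experiment count columns,
#'   `crapome_frequency` and `is_ribosomal` (see
#'   [read_spectral_counts()]).
#' @param crapome_max Maximum tolerated contaminant frequency
#'   (default 0.5; removal is strict `>`).
#' @param min_avg Minimum mean spectral count (default 4; kept if
#'   strictly `>`).
#' @param count_cols Names of the experiment count columns; defaults to
#'   every numeric column except `crapome_frequency`.
#' @return The kept rows with an added `mean_count` column, ranked.
#' @export
filter_interactors <- function(table, crapome_max = 0.5, min_avg = 4,
                               count_cols = NULL) {
  if (is.null(count_cols))
    count_cols <- names(table)[vapply(table, is.numeric, logical(1)) &
                               names(table) != "crapome_frequency"]
  if (!length(count_cols)) stop("no experiment count columns found")
  counts <- as.matrix(table[, count_cols, drop = FALSE])
  if (nrow(table) == 0) {
    out <- table
    out$mean_count <- numeric(0)
    return(out)
  }
  if (any(counts < 0)) stop("negative spectral counts")
  if (any(counts != floor(counts))) stop("spectral counts must be integers")
  if (any(table$crapome_frequency < 0 | table$crapome_frequency > 1))
    stop("crapome_frequency must be in [0, 1]")
  keep <- table$crapome_frequency <= crapome_max &
    !table$is_ribosomal &
    apply(counts > 0, 1, all) &
    rowMeans(counts) > min_avg
  out <- table[keep, , drop = FALSE]
  out$mean_count <- rowMeans(counts)[keep]
  out <- out[order(-out$mean_count, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
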
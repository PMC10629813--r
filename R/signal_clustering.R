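#' Coverage track constructor
#'
#' A labelled per-chromosome coverage signal (run-length encoded), the
#' unit plotted in tag-density heatmaps and profiles. Built from a
#' bedGraph file via [read_bedgraph()] or directly from a `GRanges` with
#' a `score` column.
#'
#' @param x `GRanges` with a numeric `score` metadata column, or an
#'   `RleList` of per-chromosome coverage.
#' @param label Track label (e.g. `"ZMYM2"`, `"TRIM28"`, `"ATAC"`).
#' @return An object of class `CoverageTrack`.
#' @export
coverage_track <- function(x, label) {
  if (is(x, "GRanges")) {
    sc <- mcols(x)$score
    if (is.null(sc)) stop("GRanges input needs a 'score' column")
    if (any(sc < 0)) stop("coverage values must be >= 0")
    cov <- coverage(x, weight = "score")
  } else if (is(x, "RleList") || is(x, "SimpleRleList")) {
    cov <- x
  } else stop("unsupported input for coverage_track")
  structure(list(label = label, cov = cov), class = "CoverageTrack")
}

#' Read a bedGraph coverage track
#'
#' @param path 4-column bedGraph file.
#' @param label Track label; defaults to the file name without extension.
#' @return A `CoverageTrack`.
#' @export
read_bedgraph <- function(path, label = NULL) {
  if (is.null(label))
    label <- sub("\\.(bedgraph|bdg|bg)$", "", basename(path), ignore.case = TRUE)
  gr <- rtracklayer::import(path, format = "bedGraph")
  coverage_track(gr, label)
}

#' Write a coverage track as bedGraph
#'
#' Zero-coverage runs are omitted (implicit zeros), so reading the file
#' back reproduces the coverage exactly.
#'
#' @param track A `CoverageTrack`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ch in names(track$cov)) {
    r <- track$cov[[ch]]
    v <- runValue(r); l <- runLength(r)
    e0 <- cumsum(as.numeric(l)); s0 <- e0 - l
    keep <- v != 0
    if (!any(keep)) next
    writeLines(paste(ch,
                     format(s0[keep], scientific = FALSE, trim = TRUE),
                     format(e0[keep], scientific = FALSE, trim = TRUE),
                     format(v[keep], scientific = FALSE, trim = TRUE,
                            digits = 10),
                     sep = "\t"), con)
  }
  invisible(path)
}

# Per-base coverage for [start1, start1 + n - 1], zero-padded beyond the
# encoded range (chromosome ends contribute zero signal).
.window_values <- function(rle, start1, n) {
  out <- numeric(n)
  if (is.null(rle)) return(out)
  L <- length(rle)
  from <- max(1L, start1)
  to <- min(L, start1 + n - 1L)
  if (from > to) return(out)
  out[(from - start1 + 1L):(to - start1 + 1L)] <-
    as.numeric(rle[from:to])
  out
}

#' Windowed multi-track signal matrix around peak centres
#'
#' For each peak, a `window`-bp window is centred on the peak centre and
#' split into `n_bins` equal bins per track; each bin holds the mean
#' per-base coverage. Regions beyond chromosome ends contribute zero.
#' Bins are half-open, left-closed; the window is
#' `[centre - window/2, centre + window/2)` in 0-based coordinates.
#'
#' @param peaks `GRanges`; row names come from `mcols(peaks)$name` when
#'   present, else `peak_<i>`.
#' @param tracks List of `CoverageTrack` objects.
#' @param window Total window width in bp (default 10 kb).
#' @param n_bins Bins per track (default 100); `window` must be divisible
#'   by `n_bins`.
#' @return A `SignalMatrix`: list with `values` (peaks x tracks*bins
#'   matrix), `peaks`, `peak_ids`, `track_labels`, `window`, `n_bins`.
#' @export
compute_signal_matrix <- function(peaks, tracks, window = 10000, n_bins = 100) {
  if (window %% n_bins != 0) stop("window must be divisible by n_bins")
  if (inherits(tracks, "CoverageTrack")) tracks <- list(tracks)
  bin_w <- window %/% n_bins
  ids <- mcols(peaks)$name
  if (is.null(ids)) ids <- sprintf("peak_%d", seq_along(peaks))
  labels <- unname(vapply(tracks, `[[`, character(1), "label"))
  centre0 <- peak_centre(peaks) - 1L            # 0-based centre
  win_start1 <- centre0 - window %/% 2L + 1L    # 1-based first base
  chr <- as.character(seqnames(peaks))
  values <- matrix(0, nrow = length(peaks), ncol = length(tracks) * n_bins,
                   dimnames = list(ids, paste(rep(labels, each = n_bins),
                                              seq_len(n_bins), sep = "|")))
  for (t in seq_along(tracks)) {
    cov <- tracks[[t]]$cov
    missing_chr <- base::setdiff(unique(chr), names(cov))
    if (length(missing_chr))
      warning(sprintf("track '%s' has no data on: %s (zero signal used)",
                      labels[t], paste(missing_chr, collapse = ", ")))
    cols <- (t - 1L) * n_bins + seq_len(n_bins)
    for (i in seq_along(peaks)) {
      v <- .window_values(cov[[chr[i]]], win_start1[i], window)
      values[i, cols] <- colMeans(matrix(v, nrow = bin_w))
    }
  }
  structure(list(values = values, peaks = peaks, peak_ids = ids,
                 track_labels = labels, window = window, n_bins = n_bins),
            class = "SignalMatrix")
}

#' @export
print.SignalMatrix <- function(x, ...) {
  cat(sprintf("SignalMatrix: %d peaks x %d tracks x %d bins (window %d bp)\n",
              nrow(x$values), length(x$track_labels), x$n_bins, x$window))
  invisible(x)
}

# Per-track scaling by the track's global 95th-percentile bin value;
# guards against all-zero tracks.
.scale_per_track <- function(mat) {
  X <- mat$values
  for (t in seq_along(mat$track_labels)) {
    cols <- (t - 1L) * mat$n_bins + seq_len(mat$n_bins)
    q <- stats::quantile(X[, cols], 0.95, names = FALSE)
    if (q > 0) X[, cols] <- X[, cols] / q
  }
  X
}

#' Cluster peaks by their windowed signal (k-means)
#'
#' Lloyd's k-means on the signal-matrix rows, best of `n_init` seeded
#' restarts by total within-cluster sum of squares. By default each
#' track's columns are first scaled by that track's global
#' 95th-percentile bin value so that one deep track cannot dominate the
#' Euclidean distance. After fitting, clusters are relabelled
#' deterministically: by descending mean signal of `repressive_track`
#' when given (so cluster 1 is the most repressive-track-rich class),
#' otherwise by descending cluster size (ties by previous label).
#'
#' @param mat A `SignalMatrix`.
#' @param k Number of clusters (default 3).
#' @param seed Master seed; restart seeds are derived from it.
#' @param n_init Number of random restarts (default 25).
#' @param scaling `"per_track_q95"` (default) or `"raw"`.
#' @param repressive_track Optional track label used to order cluster
#'   labels semantically (cluster 1 = richest in this track).
#' @param active_track Optional secondary label: among the remaining
#'   clusters, the one richest in this track becomes cluster 2 (used to
#'   separate the active co-factor class from the bare class when the
#'   repressive signal cannot order them).
#' @return A `ClusterAssignment`: list with `labels` (named integer
#'   vector over peak ids), `k`, `seed`, `inertia`, `sizes`.
#' @export
cluster_peaks <- function(mat, k = 3, seed = 1L, n_init = 25,
                          scaling = c("per_track_q95", "raw"),
                          repressive_track = NULL, active_track = NULL) {
  scaling <- match.arg(scaling)
  X <- if (scaling == "per_track_q95") .scale_per_track(mat) else mat$values
  if (nrow(unique(X)) < k)
    stop("fewer distinct signal rows than clusters (k = ", k, ")")
  set.seed(seed)
  restart_seeds <- sample.int(.Machine$integer.max - 1L, n_init)
  best <- NULL
  for (s in restart_seeds) {
    set.seed(s)
    # individual restarts may hit an empty cluster (error, skipped) or
    # stop at iter.max (warning, harmless: best-of-restarts by inertia)
    fit <- tryCatch(
      suppressWarnings(
        stats::kmeans(X, centers = k, algorithm = "Lloyd", iter.max = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed in all restarts")
  lab <- best$cluster
  # deterministic semantic relabelling
  track_key <- function(track) {
    t <- match(track, mat$track_labels)
    if (is.na(t)) stop("unknown track: ", track)
    cols <- (t - 1L) * mat$n_bins + seq_len(mat$n_bins)
    vapply(seq_len(k), function(c) {
      rows <- which(lab == c)
      if (!length(rows)) return(-Inf)
      mean(mat$values[rows, cols, drop = FALSE])
    }, numeric(1))
  }
  sizes <- tabulate(lab, k)
  if (!is.null(repressive_track)) {
    ord <- order(-track_key(repressive_track), seq_len(k))
    if (!is.null(active_track) && k > 2) {
      rest <- ord[-1]
      akey <- track_key(active_track)[rest]
      ord <- c(ord[1], rest[order(-akey, seq_along(rest))])
    }
  } else {
    ord <- order(-sizes, seq_len(k))
  }
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  lab <- relabel[lab]
  structure(list(labels = stats::setNames(as.integer(lab), mat$peak_ids),
                 k = as.integer(k), seed = seed,
                 inertia = best$tot.withinss,
                 sizes = tabulate(lab, k)),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("ClusterAssignment: k = %d, sizes = %s, inertia = %.4g\n",
              x$k, paste(x$sizes, collapse = "/"), x$inertia))
  invisible(x)
}

#' Per-cluster, per-track tag-density profiles
#'
#' Mean bin vector over member peaks, per cluster and track — the data
#' behind meta-profile (tag density) plots. Empty clusters are reported
#' with size zero and contribute no rows.
#'
#' @param mat A `SignalMatrix`.
#' @param assignment A `ClusterAssignment` covering all matrix rows.
#' @return Data frame with columns `cluster`, `track`, `bin`,
#'   `offset` (bp of the bin's left edge relative to the peak centre)
#'   and `mean`; cluster sizes in `attr(, "sizes")`.
#' @export
cluster_profiles <- function(mat, assignment) {
  lab <- assignment$labels[mat$peak_ids]
  if (anyNA(lab)) stop("assignment does not cover all matrix rows")
  bin_w <- mat$window %/% mat$n_bins
  offsets <- (seq_len(mat$n_bins) - 1L) * bin_w - mat$window %/% 2L
  rows <- list()
  for (c in seq_len(assignment$k)) {
    idx <- which(lab == c)
    if (!length(idx)) next
    means <- colMeans(mat$values[idx, , drop = FALSE])
    for (t in seq_along(mat$track_labels)) {
      cols <- (t - 1L) * mat$n_bins + seq_len(mat$n_bins)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = c, track = mat$track_labels[t],
        bin = seq_len(mat$n_bins), offset = offsets,
        mean = unname(means[cols]))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "sizes") <- tabulate(lab, assignment$k)
  out
}

#' Superimpose a new track onto an existing clustering
#'
#' Computes the per-cluster profile of a track that was not part of the
#' clustering, keeping the cluster assignment fixed (the clustering is
#' NOT recomputed) — e.g. overlaying a co-factor's signal on an existing
#' peak classification.
#'
#' @param mat The original `SignalMatrix` (supplies peaks, window, bins).
#' @param assignment The retained `ClusterAssignment`.
#' @param new_track A `CoverageTrack`.
#' @return Profile data frame as from [cluster_profiles()].
#' @export
superimpose_track <- function(mat, assignment, new_track) {
  if (!setequal(names(assignment$labels), mat$peak_ids))
    stop("peak set mismatch between matrix and assignment")
  m2 <- compute_signal_matrix(mat$peaks, list(new_track),
                              window = mat$window, n_bins = mat$n_bins)
  cluster_profiles(m2, assignment)
}
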
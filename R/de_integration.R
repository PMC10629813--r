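#' Upper-tail hypergeometric probability
#'
#' P(X >= k) when drawing `n` items from a universe of `N` containing
#' `K` successes — the enrichment statistic for set and distance-bracket
#' overlaps.
#'
#' @param k Observed overlap.
#' @param K Successes in the universe.
#' @param n Draw size.
#' @param N Universe size.
#' @return Probability in (0, 1].
#' @export
hyper_upper_p <- function(k, K, n, N) {
  stopifnot(K <= N, n <= N, k <= pmin(K, n) + 1e-9)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Call differential expression from a statistics table
#'
#' Labels genes `up`, `down` or `unchanged` using an adjusted-p and
#' fold-change rule: `up` when `adjusted_p < alpha` and
#' `2^log2_fold_change > fold_change`; `down` symmetrically. The labels
#' partition the table. Defaults follow the common count-based DE
#' convention of adjusted P < 0.01 and fold change > 1.6; an alternative
#' alpha (e.g. 0.05) can be supplied.
#'
#' @param stats Data frame with `gene_id`, `log2_fold_change` and
#'   `adjusted_p` (raw `p_value` optional; there is deliberately no
#'   silent fallback from missing adjusted p to raw p).
#' @param fold_change Fold-change threshold (linear scale, default 1.6).
#' @param alpha Adjusted-p threshold (default 0.01).
#' @return The input with an added `label` factor; up/down counts in
#'   `attr(, "counts")`.
#' @export
call_de <- function(stats, fold_change = 1.6, alpha = 0.01) {
  req <- c("gene_id", "log2_fold_change", "adjusted_p")
  miss <- base::setdiff(req, names(stats))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  lfc <- stats$log2_fold_change
  sig <- !is.na(stats$adjusted_p) & stats$adjusted_p < alpha
  up <- sig & 2^lfc > fold_change
  down <- sig & 2^(-lfc) > fold_change
  stats$label <- factor(ifelse(up, "up", ifelse(down, "down", "unchanged")),
                        levels = c("up", "down", "unchanged"))
  attr(stats, "counts") <- c(up = sum(up), down = sum(down),
                             unchanged = sum(!up & !down))
  stats
}

#' Directional gene-set overlap test
#'
#' Tests the overlap of two gene sets against a common universe with a
#' two-sided Fisher exact test on the 2x2 membership table, and also
#' returns the upper-tail hypergeometric enrichment p.
#'
#' @param A,B Character vectors of gene ids, both subsets of `universe`.
#' @param universe Character vector of all testable genes.
#' @return List with `overlap`, `fisher_p`, `hyper_p` and the 2x2
#'   `table`.
#' @export
set_overlap_test <- function(A, B, universe) {
  A <- unique(A); B <- unique(B); universe <- unique(universe)
  if (!all(A %in% universe)) stop("A is not a subset of the universe")
  if (!all(B %in% universe)) stop("B is not a subset of the universe")
  N <- length(universe)
  k <- length(base::intersect(A, B))
  tab <- matrix(c(k, length(A) - k,
                  length(B) - k, N - length(A) - length(B) + k),
                nrow = 2,
                dimnames = list(c("in_A", "not_A"), c("in_B", "not_B")))
  list(overlap = k,
       fisher_p = stats::fisher.test(tab)$p.value,
       hyper_p = hyper_upper_p(k, length(A), length(B), N),
       table = tab)
}

# Nearest peak-centre distance for every gene TSS (NA when the gene's
# chromosome carries no peak).
.tss_peak_distance <- function(genes, peaks) {
  tss <- gene_tss(genes)
  ctr <- peak_centre(peaks)
  gchr <- as.character(seqnames(genes))
  pchr <- as.character(seqnames(peaks))
  out <- rep(NA_real_, length(genes))
  for (ch in unique(gchr)) {
    p <- sort(ctr[pchr == ch])
    if (!length(p)) next
    gi <- which(gchr == ch)
    idx <- findInterval(tss[gi], p)
    lo <- ifelse(idx >= 1, p[pmax(idx, 1)], NA_real_)
    hi <- ifelse(idx < length(p), p[pmin(idx + 1, length(p))], NA_real_)
    out[gi] <- pmin(abs(tss[gi] - lo), abs(hi - tss[gi]), na.rm = TRUE)
  }
  out
}

#' Distance-bracket peak-gene hypergeometric association
#'
#' For each distance bracket `d`: `K` = universe genes whose TSS lies
#' within `d` bp of any peak centre, `k` = members of `gene_set` among
#' them, and the upper-tail hypergeometric p for drawing `k` of `K` in
#' `n = |gene_set|` from `N = |universe|`. Brackets are cumulative
#' (nested windows 0..d) by default, matching "within the indicated
#' distances"; `mode = "rings"` uses disjoint distance rings instead.
#' The universe should be the genes actually tested for differential
#' expression, so that enrichment conditions on testability. p is not
#' required to be monotone in `d`.
#'
#' @param peaks `GRanges` (optionally pre-filtered to one cluster).
#' @param gene_set Character vector of gene ids, subset of the universe.
#' @param universe Stranded `GRanges` with `gene_id`.
#' @param brackets Strictly increasing distances (bp).
#' @param mode `"cumulative"` (default) or `"rings"`.
#' @return Data frame with `bracket`, `K`, `k`, `n`, `N`, `p`.
#' @export
distance_bracket_association <- function(peaks, gene_set, universe, brackets,
                                         mode = c("cumulative", "rings")) {
  mode <- match.arg(mode)
  if (!length(universe)) stop("empty universe")
  if (any(diff(brackets) <= 0)) stop("brackets must be strictly increasing")
  ids <- mcols(universe)$gene_id
  if (!all(gene_set %in% ids)) stop("gene_set is not a subset of the universe")
  d <- .tss_peak_distance(universe, peaks)
  in_set <- ids %in% gene_set
  N <- length(universe); n <- sum(in_set)
  prev <- -1
  out <- lapply(brackets, function(b) {
    within <- if (mode == "cumulative") !is.na(d) & d <= b
              else !is.na(d) & d <= b & d > prev
    prev <<- b
    K <- sum(within); k <- sum(within & in_set)
    data.frame(bracket = b, K = K, k = k, n = n, N = N,
               p = if (K == 0) 1 else hyper_upper_p(k, K, n, N))
  })
  do.call(rbind, out)
}

#' Random-gene control for the distance-bracket association
#'
#' Draws `n_sets` seeded uniform samples (without replacement) of
#' `n_genes` ids from the universe and reports the per-bracket mean and
#' sd of their overlap counts — the grey-bar control of equal numbers of
#' randomly selected genes.
#'
#' @param peaks `GRanges`.
#' @param n_genes Genes per control set.
#' @param universe Stranded `GRanges` with `gene_id`.
#' @param brackets Strictly increasing distances (bp).
#' @param n_sets Number of control sets (default 10).
#' @param seed Seed.
#' @param mode Passed to [distance_bracket_association()].
#' @return Data frame with `bracket`, `mean_k`, `sd_k`, `K`.
#' @export
random_gene_control <- function(peaks, n_genes, universe, brackets,
                                n_sets = 10, seed = 1L,
                                mode = c("cumulative", "rings")) {
  mode <- match.arg(mode)
  ids <- mcols(universe)$gene_id
  stopifnot(n_genes <= length(ids))
  set.seed(seed)
  ks <- vapply(seq_len(n_sets), function(i) {
    s <- sample(ids, n_genes)
    distance_bracket_association(peaks, s, universe, brackets, mode)$k
  }, numeric(length(brackets)))
  ks <- matrix(ks, nrow = length(brackets))
  ref <- distance_bracket_association(
    peaks, ids[seq_len(min(1, length(ids)))], universe, brackets, mode)
  data.frame(bracket = brackets,
             mean_k = rowMeans(ks),
             sd_k = apply(ks, 1, stats::sd),
             K = ref$K)
}
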
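suppressPackageStartupMessages(library(GenomicRanges))

# Build a GRanges from 0-based half-open coordinates (the BED convention
# most fixtures below are stated in).
gr0 <- function(chrom, start0, end0, strand = NULL, ...) {
  g <- GRanges(chrom, IRanges(start0 + 1, end0))
  if (!is.null(strand)) strand(g) <- strand
  extra <- list(...)
  for (nm in names(extra)) mcols(g)[[nm]] <- extra[[nm]]
  g
}

# Gene set from 0-based coordinates with ids.
genes0 <- function(chrom, start0, end0, strand, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("g%02d", seq_along(start0))
  gr0(chrom, start0, end0, strand = strand, gene_id = ids)
}

# Random interval set for property tests.
random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e5,
                             max_len = 2000) {
  s0 <- floor(runif(n, 0, max_pos))
  len <- floor(runif(n, 1, max_len))
  gr0(sample(chroms, n, replace = TRUE), s0, s0 + len)
}

# A constant-value coverage track over given chromosome lengths.
constant_track <- function(label, value, chrom_lengths) {
  covs <- lapply(chrom_lengths, function(L) S4Vectors::Rle(value, L))
  coverage_track(methods::as(covs, "SimpleRleList"), label)
}

# Track with rectangular plateaus: data frame (chrom, start0, end0, value).
plateau_track <- function(label, plateaus, chrom_lengths) {
  covs <- lapply(names(chrom_lengths), function(ch) {
    v <- numeric(chrom_lengths[[ch]])
    rows <- plateaus[plateaus$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(rows)))
      v[(rows$start0[i] + 1):rows$end0[i]] <- rows$value[i]
    S4Vectors::Rle(v)
  })
  names(covs) <- names(chrom_lengths)
  coverage_track(methods::as(covs, "SimpleRleList"), label)
}

# Brute-force oracles -------------------------------------------------------

# All-pairs mutual-overlap oracle on 0-based coordinates.
oracle_mutual <- function(a, b, frac = 0.3) {
  if (as.character(seqnames(a)) != as.character(seqnames(b))) return(FALSE)
  s <- max(start(a), start(b)); e <- min(end(a), end(b))
  ov <- max(0, e - s + 1)
  ov >= frac * width(a) && ov >= frac * width(b)
}

# Exhaustive point-to-interval distance oracle.
oracle_distance <- function(point_chrom, point_pos, targets) {
  keep <- as.character(seqnames(targets)) == point_chrom
  if (!any(keep)) return(NA_real_)
  min(pmax(start(targets)[keep] - point_pos,
           point_pos - end(targets)[keep], 0))
}

# Exact upper-tail hypergeometric by combinatorial summation.
oracle_hyper_upper <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Exact two-sided Fisher p by enumerating all tables with fixed margins.
oracle_fisher_two_sided <- function(k, K, n, N) {
  lo <- max(0, n + K - N); hi <- min(K, n)
  probs <- vapply(lo:hi, function(j)
    choose(K, j) * choose(N - K, n - j) / choose(N, n), numeric(1))
  p_obs <- probs[k - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# IUPAC motif as a regular expression (independent matching oracle).
iupac_regex <- function(motif) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste(map[strsplit(toupper(motif), "")[[1]]], collapse = "")
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
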
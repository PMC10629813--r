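#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet reverseComplement matchPattern vmatchPattern subseq
NULL

.categories <- c("promoter", "tts", "exonic", "intronic", "distal_intergenic")

# Strand-aware annotation windows (1-based closed), clipped at position 1.
# promoter: [TSS-1000, TSS+100] on +, mirrored on -; TTS windows likewise.
# Gene body (exon/intron territory): [start+100, end-100] on either strand.
.feature_windows <- function(genes) {
  tss <- gene_tss(genes)
  tts <- gene_tts(genes)
  plus <- as.character(strand(genes)) == "+"
  chr <- as.character(seqnames(genes))
  prom <- GRanges(chr, IRanges(pmax(1L, ifelse(plus, tss - 1000L, tss - 100L)),
                               ifelse(plus, tss + 100L, tss + 1000L)))
  ttsw <- GRanges(chr, IRanges(pmax(1L, ifelse(plus, tts - 100L, tts - 1000L)),
                               ifelse(plus, tts + 1000L, tts + 100L)))
  bs <- start(genes) + 100L
  be <- end(genes) - 100L
  has_body <- be >= bs
  body <- GRanges(chr[has_body], IRanges(bs[has_body], be[has_body]))
  exons <- mcols(genes)$exons
  if (is.null(exons)) {
    exonic <- body   # genes without exon lists are treated as single-exon
    intronic <- GRanges()
  } else {
    ex <- unlist(exons)
    exonic <- GenomicRanges::intersect(GenomicRanges::reduce(ex),
                                       GenomicRanges::reduce(body))
    intronic <- GenomicRanges::setdiff(GenomicRanges::reduce(body), exonic)
  }
  list(promoter = prom, tts = ttsw, body = body,
       exonic = exonic, intronic = intronic)
}

#' Classify peak summits into genomic categories
#'
#' Five-way, summit-anchored classification: promoter
#' (TSS -1 kb to +0.1 kb, strand-aware), TTS (-0.1 kb to +1 kb around the
#' termination site), exonic and intronic (within the gene body from
#' TSS+0.1 kb to TTS-0.1 kb), and distal intergenic otherwise. A peak is
#' linked to a region if its summit lies in the region; precedence is
#' promoter > tts > exonic > intronic across all genes, making the
#' categories exhaustive and mutually exclusive. Peaks without a summit
#' fall back to their centre (logged).
#'
#' @param peaks `GRanges`, ideally with a `summit` column.
#' @param genes Stranded `GRanges` with `gene_id`; an optional `exons`
#'   metadata column (`GRangesList`) refines the exon/intron split,
#'   otherwise genes are treated as single-exon.
#' @return Factor with levels `promoter, tts, exonic, intronic,
#'   distal_intergenic`.
#' @export
classify_summits <- function(peaks, genes) {
  pos <- GRanges(seqnames(peaks), IRanges(peak_summit(peaks), width = 1L))
  out <- factor(rep("distal_intergenic", length(peaks)), levels = .categories)
  if (!length(genes) || !length(peaks)) return(out)
  .check_chrom_overlap(peaks, genes, "peaks", "genes")
  w <- .feature_windows(genes)
  in_prom <- IRanges::overlapsAny(pos, w$promoter)
  in_tts <- IRanges::overlapsAny(pos, w$tts)
  if (is.null(mcols(genes)$exons)) {
    in_ex <- IRanges::overlapsAny(pos, w$exonic)
    in_in <- rep(FALSE, length(pos))
  } else {
    in_ex <- IRanges::overlapsAny(pos, w$exonic)
    in_in <- IRanges::overlapsAny(pos, w$intronic)
  }
  out[in_in] <- "intronic"
  out[in_ex] <- "exonic"
  out[in_tts] <- "tts"
  out[in_prom] <- "promoter"
  out
}

#' Genomic distribution of peaks and the genome-wide baseline
#'
#' Proportion of peaks (by summit) in each of the five genomic
#' categories, plus the genome-wide baseline computed as the fraction of
#' genome base pairs falling into each category under the same windows
#' and precedence.
#'
#' @param peaks `GRanges` (non-empty).
#' @param genes Stranded `GRanges` with `gene_id`.
#' @param chrom_lengths Named vector of chromosome lengths (bp), needed
#'   for the baseline; taken from `seqlengths(genes)` when omitted.
#' @return List with `peaks` and `genome`, each a named proportion
#'   vector over the five categories (summing to 1).
#' @export
genomic_distribution <- function(peaks, genes, chrom_lengths = NULL) {
  if (!length(peaks)) stop("empty peak list")
  cls <- classify_summits(peaks, genes)
  props <- as.numeric(table(cls)) / length(peaks)
  names(props) <- levels(cls)
  if (is.null(chrom_lengths)) {
    sl <- GenomeInfoDb::seqlengths(genes)
    if (all(is.na(sl))) stop("chrom_lengths required for the genome baseline")
    chrom_lengths <- sl[!is.na(sl)]
  }
  total <- sum(as.numeric(chrom_lengths))
  clip <- function(gr) {
    gr <- gr[as.character(seqnames(gr)) %in% names(chrom_lengths)]
    lim <- as.integer(chrom_lengths[as.character(seqnames(gr))])
    s <- pmax(1L, start(gr)); e <- pmin(lim, end(gr))
    keep <- e >= s
    GenomicRanges::reduce(GRanges(seqnames(gr)[keep],
                                  IRanges(s[keep], e[keep])))
  }
  w <- .feature_windows(genes)
  prom <- clip(w$promoter)
  ttsw <- GenomicRanges::setdiff(clip(w$tts), prom)
  used <- GenomicRanges::union(prom, ttsw)
  if (is.null(mcols(genes)$exons)) {
    exn <- GenomicRanges::setdiff(clip(w$exonic), used)
    itr <- GRanges()
  } else {
    exn <- GenomicRanges::setdiff(clip(w$exonic), used)
    itr <- GenomicRanges::setdiff(clip(w$intronic),
                                  GenomicRanges::union(used, exn))
  }
  bp <- c(promoter = sum(as.numeric(width(prom))),
          tts = sum(as.numeric(width(ttsw))),
          exonic = sum(as.numeric(width(exn))),
          intronic = sum(as.numeric(width(itr))))
  genome <- c(bp, distal_intergenic = total - sum(bp)) / total
  list(peaks = props, genome = genome[.categories])
}

#' Retrotransposon composition of peak clusters
#'
#' At `level = "class"`: for each cluster, the fraction of peaks
#' containing (overlapping by at least `min_overlap_bp`) at least one
#' element of each repeat class, with a genome-wide background (fraction
#' of genome bp covered by each class when `chrom_lengths` is given).
#' At `level = "family"`: restricted to families of `parent_class`,
#' reported as proportions among peaks containing that class (per-peak
#' family memberships normalised so each cluster sums to 1).
#'
#' @param peaks `GRanges`.
#' @param clusters Integer/character vector of cluster labels, parallel
#'   to `peaks`, or a `ClusterAssignment` (matched by peak name).
#' @param repeats `GRanges` from `read_intervals(format = "repeat_tsv")`.
#' @param level `"class"` or `"family"`.
#' @param parent_class Repeat class whose families are profiled at
#'   family level (default `"LTR"`).
#' @param min_overlap_bp Minimum overlap for "containing" (default 1).
#' @param chrom_lengths Optional named lengths for the class-level
#'   genome background.
#' @return Data frame: `cluster`, `class` or `family`, `fraction`
#'   (and `n_peaks`); class level carries the background as
#'   `attr(, "background")`.
#' @export
repeat_composition <- function(peaks, clusters, repeats,
                               level = c("class", "family"),
                               parent_class = "LTR",
                               min_overlap_bp = 1L,
                               chrom_lengths = NULL) {
  level <- match.arg(level)
  if (inherits(clusters, "ClusterAssignment")) {
    ids <- mcols(peaks)$name
    if (is.null(ids)) stop("peaks need names to match a ClusterAssignment")
    clusters <- unname(clusters$labels[ids])
  }
  stopifnot(length(clusters) == length(peaks))
  hits <- findOverlaps(peaks, repeats, minoverlap = as.integer(min_overlap_bp))
  pk <- queryHits(hits)
  rcls <- mcols(repeats)$repeat_class[subjectHits(hits)]
  rfam <- mcols(repeats)$repeat_family[subjectHits(hits)]
  labs <- sort(unique(clusters))
  if (level == "class") {
    classes <- c("LTR", "SINE", "LINE", "other")
    out <- do.call(rbind, lapply(labs, function(cl) {
      in_cl <- which(clusters == cl)
      frac <- vapply(classes, function(rc)
        length(unique(pk[pk %in% in_cl & rcls == rc])) /
          max(1L, length(in_cl)), numeric(1))
      data.frame(cluster = cl, class = classes, fraction = unname(frac),
                 n_peaks = length(in_cl))
    }))
    if (!is.null(chrom_lengths)) {
      total <- sum(as.numeric(chrom_lengths))
      bg <- vapply(classes, function(rc) {
        r <- GenomicRanges::reduce(repeats[mcols(repeats)$repeat_class == rc])
        sum(as.numeric(width(r))) / total
      }, numeric(1))
      attr(out, "background") <- bg
    }
    out
  } else {
    fams <- sort(unique(rfam[rcls == parent_class]))
    do.call(rbind, lapply(labs, function(cl) {
      in_cl <- which(clusters == cl)
      counts <- vapply(fams, function(f)
        length(unique(pk[pk %in% in_cl & rcls == parent_class & rfam == f])),
        numeric(1))
      tot <- sum(counts)
      data.frame(cluster = cl, family = fams,
                 fraction = if (tot > 0) unname(counts) / tot
                            else rep(NA_real_, length(fams)),
                 n_peaks = length(in_cl))
    }))
  }
}

.iupac_ok <- function(motif) {
  all(strsplit(toupper(motif), "")[[1]] %in%
        strsplit("ACGTRYSWKMBDHVN", "")[[1]])
}

#' Scan regions for an IUPAC consensus motif
#'
#' Each region's window (`window` bp centred on the summit, clipped at
#' chromosome ends) is scanned on both strands for an exact
#' IUPAC-compatible match of `motif`. Returns the count and fraction of
#' regions with at least one match, with per-region hit offsets.
#' Background frequencies are obtained by scanning caller-provided
#' control regions (e.g. from [random_background_regions()]) identically.
#'
#' @param regions `GRanges` (summit used when present, else centre).
#' @param sequences Named `DNAStringSet` keyed by chromosome, or a FASTA
#'   path.
#' @param motif IUPAC string (codes `ACGTRYSWKMBDHVN`).
#' @param window Window width in bp (default 101).
#' @return List with `n_regions`, `n_hit`, `fraction` and a `hits` data
#'   frame (`region`, `offset` within the window, 1-based, `strand`).
#' @export
consensus_scan <- function(regions, sequences, motif, window = 101) {
  if (!.iupac_ok(motif))
    stop("motif contains non-IUPAC characters: ", motif)
  if (is.character(sequences) && length(sequences) == 1) {
    sequences <- readDNAStringSet(sequences)
    names(sequences) <- sub("\\s.*$", "", names(sequences))
  }
  chr <- as.character(seqnames(regions))
  missing_chr <- base::setdiff(unique(chr), names(sequences))
  if (length(missing_chr))
    stop("no sequence for chromosome(s): ", paste(missing_chr, collapse = ", "))
  anchor <- peak_summit(regions, quiet = TRUE)
  half <- (window - 1L) %/% 2L
  froms <- pmax(1L, anchor - half)
  tos <- pmin(as.integer(Biostrings::width(sequences)[match(chr, names(sequences))]),
              anchor + (window - 1L - half))
  wins <- DNAStringSet(vapply(seq_along(regions), function(i)
    as.character(subseq(sequences[[chr[i]]], froms[i], tos[i])),
    character(1)))
  fwd <- vmatchPattern(DNAString(toupper(motif)), wins, fixed = FALSE)
  rev <- vmatchPattern(reverseComplement(DNAString(toupper(motif))), wins,
                       fixed = FALSE)
  ids <- mcols(regions)$name
  if (is.null(ids)) ids <- sprintf("region_%d", seq_along(regions))
  hit_rows <- list()
  n_hit <- 0L
  for (i in seq_along(regions)) {
    f <- start(fwd[[i]]); r <- start(rev[[i]])
    if (length(f) || length(r)) {
      n_hit <- n_hit + 1L
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        region = ids[i],
        offset = c(f, r),
        strand = rep(c("+", "-"), c(length(f), length(r))))
    }
  }
  list(n_regions = length(regions), n_hit = n_hit,
       fraction = if (length(regions)) n_hit / length(regions) else NA_real_,
       hits = if (length(hit_rows)) do.call(rbind, hit_rows)
              else data.frame(region = character(0), offset = integer(0),
                              strand = character(0)))
}

#' Random width-matched background regions
#'
#' Generates `times` uniformly placed control regions per input region
#' on the same chromosomes (chromosome drawn proportional to length),
#' width-matched, seeded — the default background for motif frequency
#' comparisons.
#'
#' @param regions `GRanges` whose widths are matched.
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param times Count multiplier (default 10).
#' @param seed Seed.
#' @return `GRanges` with summits set to region centres.
#' @export
random_background_regions <- function(regions, chrom_lengths, times = 10,
                                      seed = 1L) {
  set.seed(seed)
  widths <- rep(width(regions), times)
  chrs <- sample(names(chrom_lengths), length(widths), replace = TRUE,
                 prob = as.numeric(chrom_lengths))
  lim <- as.numeric(chrom_lengths[chrs])
  starts <- floor(stats::runif(length(widths), 1, pmax(2, lim - widths + 1)))
  gr <- GRanges(chrs, IRanges(as.integer(starts),
                              width = as.integer(widths)))
  mcols(gr)$name <- sprintf("bg_%d", seq_along(gr))
  mcols(gr)$summit <- peak_centre(gr)
  gr
}
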
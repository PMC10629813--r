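#' @importFrom GenomicRanges GRanges seqnames start end width strand strand<-
#'   mcols mcols<- findOverlaps coverage reduce setdiff intersect union
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits Rle runValue runLength
#' @importFrom methods is
NULL

# Families accepted for each repeat class. "other" accepts any family.
.repeat_class_families <- list(
  LTR  = c("ERV1", "ERVK", "ERVL", "ERVL-MaLR", "Gypsy", "LTR"),
  SINE = c("Alu", "MIR", "tRNA", "Deu"),
  LINE = c("L1", "L2", "CR1", "RTE", "Penelope", "Dong-R4")
)

#' Repeat class/family lookup
#'
#' The fixed mapping used to validate repeat annotations at load time:
#' each retrotransposon family must belong to its declared class
#' (e.g. ERV1 and ERVL are LTR families; Alu and MIR are SINE families).
#' Class `other` accepts any family string.
#'
#' @return Named list mapping class to accepted family names.
#' @export
repeat_family_classes <- function() .repeat_class_families

.check_chrom_overlap <- function(a, b, what_a = "set A", what_b = "set B") {
  ca <- unique(as.character(seqnames(a)))
  cb <- unique(as.character(seqnames(b)))
  if (length(ca) && length(cb) && !length(base::intersect(ca, cb)))
    warning(sprintf("%s and %s share no chromosome names (e.g. %s vs %s)",
                    what_a, what_b, ca[1], cb[1]))
  invisible(NULL)
}

.read_tab <- function(path, n_col, header = FALSE, what = "file") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  first_data <- 1L
  if (header && length(lines)) first_data <- 2L
  body <- lines[seq_along(lines) >= first_data]
  body_idx <- which(nzchar(body))
  if (!length(body_idx))
    return(list(df = NULL, lines = integer(0)))
  fields <- strsplit(body[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < n_col)
  if (length(bad)) {
    ln <- body_idx[bad[1]] + first_data - 1L
    stop(sprintf("%s: line %d has %d columns, expected at least %d",
                 what, ln, nf[bad[1]], n_col))
  }
  df <- as.data.frame(do.call(rbind, lapply(fields, `[`, seq_len(n_col))),
                      stringsAsFactors = FALSE)
  list(df = df, lines = body_idx + first_data - 1L,
       header = if (header && length(lines)) lines[1] else NULL)
}

.num_col <- function(x, lines, what, col) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad))
    stop(sprintf("%s: line %d: non-numeric value '%s' in column %d",
                 what, lines[bad[1]], x[bad[1]], col))
  v
}

.gr_from_bed <- function(df, lines, what) {
  start0 <- .num_col(df[[2]], lines, what, 2L)
  end0 <- .num_col(df[[3]], lines, what, 3L)
  bad <- which(end0 <= start0)
  if (length(bad))
    stop(sprintf("%s: line %d: end (%s) must exceed start (%s)",
                 what, lines[bad[1]], end0[bad[1]], start0[bad[1]]))
  if (any(start0 < 0))
    stop(what, ": negative start coordinate")
  GRanges(df[[1]], IRanges(start0 + 1, end0))
}

#' Read genomic intervals from standard formats
#'
#' Parses BED-family and tabular annotation formats into `GRanges`,
#' converting to the 1-based closed convention used internally. The
#' narrowPeak summit offset is converted to an absolute position
#' (`summit = start + offset`; offset `-1` means absent). Input record
#' order is preserved; malformed lines raise errors naming the line.
#'
#' Formats: `bed3`, `bed6`, `narrowPeak` (ENCODE 10-column),
#' `tad_bed` (BED3; per-chromosome overlap between TADs is an error),
#' `repeat_tsv` (header `chrom start end strand repeat_name repeat_class
#' repeat_family`; family/class pairs validated against
#' [repeat_family_classes()]; exact duplicates dropped), and `gene_tsv`
#' (header `chrom start end strand gene_id`; an optional first line
#' `#coordinates=1-based` declares 1-based closed input, converted at load).
#'
#' @param path File path.
#' @param format One of the format tags above.
#' @return A `GRanges` with format-specific metadata columns
#'   (`summit`, `tad_id`, `gene_id`, `repeat_class`, ...).
#' @export
read_intervals <- function(path,
                           format = c("bed3", "bed6", "narrowPeak",
                                      "tad_bed", "repeat_tsv", "gene_tsv")) {
  format <- match.arg(format)
  switch(format,
    bed3 = {
      p <- .read_tab(path, 3L, what = path)
      if (is.null(p$df)) return(GRanges())
      .gr_from_bed(p$df, p$lines, path)
    },
    bed6 = {
      p <- .read_tab(path, 6L, what = path)
      if (is.null(p$df)) return(GRanges())
      gr <- .gr_from_bed(p$df, p$lines, path)
      strand(gr) <- ifelse(p$df[[6]] %in% c("+", "-"), p$df[[6]], "*")
      mcols(gr)$name <- p$df[[4]]
      mcols(gr)$score <- suppressWarnings(as.numeric(p$df[[5]]))
      gr
    },
    narrowPeak = {
      p <- .read_tab(path, 10L, what = path)
      if (is.null(p$df)) return(GRanges())
      gr <- .gr_from_bed(p$df, p$lines, path)
      mcols(gr)$name <- p$df[[4]]
      mcols(gr)$score <- .num_col(p$df[[5]], p$lines, path, 5L)
      strand(gr) <- ifelse(p$df[[6]] %in% c("+", "-"), p$df[[6]], "*")
      mcols(gr)$signalValue <- .num_col(p$df[[7]], p$lines, path, 7L)
      mcols(gr)$pValue <- .num_col(p$df[[8]], p$lines, path, 8L)
      mcols(gr)$qValue <- .num_col(p$df[[9]], p$lines, path, 9L)
      off <- .num_col(p$df[[10]], p$lines, path, 10L)
      start0 <- start(gr) - 1L
      summit <- ifelse(off < 0, NA_integer_, as.integer(start0 + off + 1L))
      bad <- which(!is.na(summit) & (summit < start(gr) | summit > end(gr)))
      if (length(bad))
        stop(sprintf("%s: line %d: summit offset outside the peak",
                     path, p$lines[bad[1]]))
      mcols(gr)$summit <- summit
      gr
    },
    tad_bed = {
      p <- .read_tab(path, 3L, what = path)
      if (is.null(p$df)) return(GRanges())
      gr <- .gr_from_bed(p$df, p$lines, path)
      mcols(gr)$tad_id <- sprintf("tad_%04d", seq_along(gr))
      validate_tads(gr)
      gr
    },
    repeat_tsv = {
      p <- .read_tab(path, 7L, header = TRUE, what = path)
      if (is.null(p$header) || !grepl("^chrom\t", p$header))
        stop(path, ": repeat_tsv requires a header line starting with 'chrom'")
      if (is.null(p$df)) return(GRanges())
      gr <- .gr_from_bed(p$df, p$lines, path)
      strand(gr) <- ifelse(p$df[[4]] %in% c("+", "-"), p$df[[4]], "*")
      mcols(gr)$repeat_name <- p$df[[5]]
      mcols(gr)$repeat_class <- p$df[[6]]
      mcols(gr)$repeat_family <- p$df[[7]]
      cls <- mcols(gr)$repeat_class
      fam <- mcols(gr)$repeat_family
      bad_cls <- which(!cls %in% c(names(.repeat_class_families), "other"))
      if (length(bad_cls))
        stop(sprintf("%s: line %d: unknown repeat class '%s'",
                     path, p$lines[bad_cls[1]], cls[bad_cls[1]]))
      known <- cls %in% names(.repeat_class_families)
      bad_fam <- which(known &
                       !mapply(function(c, f) f %in% .repeat_class_families[[c]],
                               cls, fam))
      if (length(bad_fam))
        stop(sprintf("%s: line %d: family '%s' is not a %s family",
                     path, p$lines[bad_fam[1]], fam[bad_fam[1]], cls[bad_fam[1]]))
      key <- paste(seqnames(gr), start(gr), end(gr), mcols(gr)$repeat_name)
      gr[!duplicated(key)]
    },
    gene_tsv = {
      lines <- readLines(path)
      one_based <- FALSE
      if (length(lines) && grepl("^#coordinates=", lines[1])) {
        one_based <- identical(sub("^#coordinates=", "", lines[1]), "1-based")
        tmp <- tempfile()
        on.exit(unlink(tmp), add = TRUE)
        writeLines(lines[-1], tmp)
        path2 <- tmp
      } else path2 <- path
      p <- .read_tab(path2, 5L, header = TRUE, what = path)
      if (is.null(p$header) || !grepl("^chrom\t", p$header))
        stop(path, ": gene_tsv requires a header line starting with 'chrom'")
      if (is.null(p$df)) return(GRanges())
      df <- p$df
      if (one_based) {
        # convert 1-based closed input to the BED convention before parsing
        df[[2]] <- as.character(.num_col(df[[2]], p$lines, path, 2L) - 1)
      }
      gr <- .gr_from_bed(df, p$lines, path)
      if (any(!df[[4]] %in% c("+", "-")))
        stop(path, ": gene strand must be '+' or '-'")
      strand(gr) <- df[[4]]
      mcols(gr)$gene_id <- df[[5]]
      gr
    })
}

#' Write genomic intervals in a standard format
#'
#' Inverse of [read_intervals()]: converts back to 0-based half-open
#' coordinates for the BED-family formats so that a write/read round trip
#' reproduces coordinates exactly.
#'
#' @param x `GRanges` as produced by [read_intervals()] or the simulator.
#' @param path Output file path.
#' @param format Same tags as [read_intervals()].
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path,
                            format = c("bed3", "bed6", "narrowPeak",
                                       "tad_bed", "repeat_tsv", "gene_tsv")) {
  format <- match.arg(format)
  chrom <- as.character(seqnames(x))
  s0 <- format(start(x) - 1L, scientific = FALSE, trim = TRUE)
  e0 <- format(end(x), scientific = FALSE, trim = TRUE)
  str <- as.character(strand(x))
  str[str == "*"] <- "."
  m <- mcols(x)
  lines <- switch(format,
    bed3 = paste(chrom, s0, e0, sep = "\t"),
    bed6 = paste(chrom, s0, e0,
                 if (!is.null(m$name)) m$name else ".",
                 if (!is.null(m$score)) m$score else 0,
                 str, sep = "\t"),
    narrowPeak = {
      off <- if (!is.null(m$summit))
        ifelse(is.na(m$summit), -1L, m$summit - start(x)) else -1L
      paste(chrom, s0, e0,
            if (!is.null(m$name)) m$name else ".",
            if (!is.null(m$score)) m$score else 0,
            str,
            if (!is.null(m$signalValue)) m$signalValue else 0,
            if (!is.null(m$pValue)) m$pValue else -1,
            if (!is.null(m$qValue)) m$qValue else -1,
            off, sep = "\t")
    },
    tad_bed = paste(chrom, s0, e0, sep = "\t"),
    repeat_tsv = c("chrom\tstart\tend\tstrand\trepeat_name\trepeat_class\trepeat_family",
                   if (length(x))
                     paste(chrom, s0, e0, str, m$repeat_name,
                           m$repeat_class, m$repeat_family, sep = "\t")),
    gene_tsv = c("chrom\tstart\tend\tstrand\tgene_id",
                 if (length(x))
                   paste(chrom, s0, e0, str, m$gene_id, sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Validate a TAD set
#'
#' TADs on one chromosome must be non-overlapping; any overlap is an error.
#'
#' @param tads `GRanges` of TAD intervals.
#' @return `tads`, invisibly.
#' @export
validate_tads <- function(tads) {
  if (length(tads) > 1) {
    hits <- findOverlaps(tads, tads, minoverlap = 1L)
    hits <- hits[queryHits(hits) != subjectHits(hits)]
    if (length(hits))
      stop(sprintf("overlapping TADs: records %d and %d",
                   queryHits(hits)[1], subjectHits(hits)[1]))
  }
  invisible(tads)
}

#' Peak centre positions
#'
#' The centre anchor used for signal windows, TAD containment and
#' peak-gene distances: `floor((start + end) / 2)` in 0-based half-open
#' coordinates, returned here as a 1-based position.
#'
#' @param x `GRanges`.
#' @return Integer vector of 1-based centre positions.
#' @export
peak_centre <- function(x) {
  as.integer(((start(x) + end(x) - 1L) %/% 2L) + 1L)
}

#' Peak summit positions with centre fallback
#'
#' Returns the absolute summit position (1-based) where present, and the
#' interval centre where absent (with a message, since feature
#' classification is summit-anchored).
#'
#' @param x `GRanges`, optionally with a `summit` metadata column.
#' @param quiet Suppress the fallback message.
#' @return Integer vector of 1-based positions.
#' @export
peak_summit <- function(x, quiet = FALSE) {
  s <- mcols(x)$summit
  ctr <- peak_centre(x)
  if (is.null(s)) {
    if (!quiet && length(x)) message("no summits available; using peak centres")
    return(ctr)
  }
  miss <- is.na(s)
  if (any(miss) && !quiet)
    message(sum(miss), " peak(s) without summit; using centres for those")
  out <- ifelse(miss, ctr, as.integer(s))
  as.integer(out)
}

#' Gene transcription start sites
#' @param genes Stranded `GRanges`.
#' @return Integer vector of 1-based TSS positions (start for `+`,
#'   end for `-`).
#' @export
gene_tss <- function(genes) {
  str <- as.character(strand(genes))
  if (any(!str %in% c("+", "-"))) stop("genes must be stranded (+/-)")
  as.integer(ifelse(str == "+", start(genes), end(genes)))
}

#' Gene transcription termination sites
#' @param genes Stranded `GRanges`.
#' @return Integer vector of 1-based TTS positions (end for `+`,
#'   start for `-`).
#' @export
gene_tts <- function(genes) {
  str <- as.character(strand(genes))
  if (any(!str %in% c("+", "-"))) stop("genes must be stranded (+/-)")
  as.integer(ifelse(str == "+", end(genes), start(genes)))
}

#' Mutual fractional overlap between intervals
#'
#' Two intervals count as overlapping only when the shared span covers at
#' least `frac` of each interval's length (default 30%). Symmetric in its
#' arguments; different chromosomes or no overlap give `FALSE`.
#'
#' @param a,b `GRanges` of equal length (or length one, recycled);
#'   tested pairwise.
#' @param frac Required fraction of each length, in (0, 1].
#' @return Logical vector.
#' @export
mutual_overlap <- function(a, b, frac = 0.3) {
  stopifnot(frac > 0, frac <= 1)
  n <- max(length(a), length(b))
  if (length(a) == 1) a <- rep(a, n)
  if (length(b) == 1) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  same <- as.character(seqnames(a)) == as.character(seqnames(b))
  ov <- pmax(0L, pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L)
  same & ov >= frac * width(a) & ov >= frac * width(b)
}

#' Overlap summary between two peak sets
#'
#' Counts peaks in each set with at least one mutual-overlap partner in
#' the other set (the Venn-style shared/exclusive decomposition), and
#' returns the qualifying pairs.
#'
#' @param P,Q `GRanges` peak sets.
#' @param frac Mutual overlap fraction, see [mutual_overlap()].
#' @return List with `shared_p`, `shared_q`, `p_only`, `q_only` counts and
#'   a `pairs` data frame of qualifying index pairs.
#' @export
overlap_peak_sets <- function(P, Q, frac = 0.3) {
  .check_chrom_overlap(P, Q, "P", "Q")
  hits <- findOverlaps(P, Q, minoverlap = 1L)
  qi <- queryHits(hits); si <- subjectHits(hits)
  keep <- if (length(hits)) mutual_overlap(P[qi], Q[si], frac) else logical(0)
  qi <- qi[keep]; si <- si[keep]
  shared_p <- length(unique(qi))
  shared_q <- length(unique(si))
  list(shared_p = shared_p,
       shared_q = shared_q,
       p_only = length(P) - shared_p,
       q_only = length(Q) - shared_q,
       pairs = data.frame(p_index = qi, q_index = si))
}

#' Distance from points to nearest target interval
#'
#' Zero when a point lies inside a target; otherwise base pairs to the
#' nearest target edge. Points on chromosomes with no target get `NA`
#' (excluded from summaries). Ties are resolved towards the first target
#' in sorted genomic order, which leaves the distance unchanged.
#'
#' @param points `GRanges` of query positions (centres are used for
#'   intervals wider than 1 bp) or a data frame with `chrom` and `pos`
#'   (1-based) columns.
#' @param targets `GRanges` of target intervals or positions.
#' @return Numeric vector of distances (bp), `NA` where undefined.
#' @export
distance_to_nearest <- function(points, targets) {
  if (is.data.frame(points))
    points <- GRanges(points$chrom, IRanges(points$pos, points$pos))
  pos <- ifelse(width(points) > 1L, peak_centre(points), start(points))
  pchr <- as.character(seqnames(points))
  tchr <- as.character(seqnames(targets))
  out <- rep(NA_real_, length(points))
  for (ch in unique(pchr)) {
    ti <- which(tchr == ch)
    if (!length(ti)) next
    pi <- which(pchr == ch)
    ts <- start(targets)[ti]; te <- end(targets)[ti]
    for (j in pi) {
      d <- pmax(ts - pos[j], pos[j] - te, 0L)
      out[j] <- min(d)
    }
  }
  out
}
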
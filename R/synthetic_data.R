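#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator with
#' defaults chosen to emulate the analysed study system at desk scale:
#' two 10-Mb chromosomes tiled by 200-500 kb TADs (with occasional
#' inter-TAD gaps), ~1200 strand-aware genes, three planted peak
#' archetypes of 200 peaks each over six coverage tracks (archetype 1:
#' high ZMYM2/TRIM28/SUMO, low ATAC/H3K18ac; archetype 2: high
#' ZMYM2/ADNP/ATAC/H3K18ac; archetype 3: ZMYM2 only), negative-binomial
#' bump heights over a constant background, repeat placement conditioned
#' on archetype (LTR/ERV1 with archetype 1, SINE Alu+MIR with
#' archetype 2, LTR/ERVL with archetype 3), a DE table with a baseline
#' rate of genuinely regulated genes plus regionally planted
#' up-regulation inside TADs containing archetype-1 peaks, a planted
#' IUPAC consensus in archetype-2 peak sequences, and a spectral-count
#' table with known keep/remove structure.
#'
#' All randomness derives from the single `seed` through named
#' sub-streams, so the same config gives a byte-identical bundle.
#'
#' @param seed Master seed.
#' @param ... Overrides for any default listed above (see
#'   `names(sim_config())`).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    chrom_lengths = c(chr1 = 1e7, chr2 = 1e7),
    tad_length_range = c(2e5, 5e5),
    tad_gap_prob = 0.2,
    tad_gap_range = c(1e4, 5e4),
    n_genes = 1200L,
    gene_length_range = c(2e3, 2e4),
    p_plus_strand = 0.5,
    n_peaks = c(200L, 200L, 200L),
    peak_width_range = c(200, 600),
    peak_in_tad_rate = 0.95,
    tracks = c("ZMYM2", "TRIM28", "SUMO", "ATAC", "H3K18ac", "ADNP"),
    archetype_means = rbind(
      c(ZMYM2 = 30, TRIM28 = 25, SUMO = 20, ATAC = 2, H3K18ac = 2, ADNP = 3),
      c(ZMYM2 = 25, TRIM28 = 3, SUMO = 4, ATAC = 20, H3K18ac = 18, ADNP = 22),
      c(ZMYM2 = 20, TRIM28 = 2, SUMO = 3, ATAC = 3, H3K18ac = 3, ADNP = 3)),
    nb_size = 20,
    background = 0.5,
    bump_sd = 400,
    track_bin = 50L,
    repeat_rates = data.frame(
      archetype = c(1L, 2L, 2L, 3L),
      class = c("LTR", "SINE", "SINE", "LTR"),
      family = c("ERV1", "Alu", "MIR", "ERVL"),
      rate = c(0.8, 0.35, 0.35, 0.75)),
    n_background_repeats = 400L,
    repeat_width_range = c(150, 500),
    baseline_de_frac = 0.10,
    de_shift = 1.5,
    lfc_sd = 0.25,
    regional_frac = 0.5,
    regional_shift = 1.5,
    motif = "CGCCCYCTNSTG",
    motif_rate = 0.15,
    motif_archetype = 2L,
    n_true_interactors = 15L,
    n_contaminants = 15L,
    n_ribosomal = 5L,
    n_dropout = 5L,
    true_count_mean = 12,
    contaminant_count_mean = 6,
    n_experiments = 3L)
  over <- list(...)
  unknown <- base::setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (any(unlist(cfg$n_peaks) < 0) || cfg$n_genes <= 0)
    stop("counts must be non-negative (n_genes positive)")
  if (cfg$tad_length_range[1] > min(cfg$chrom_lengths))
    stop("TADs longer than chromosomes")
  structure(cfg, class = "sim_config")
}

# Named sub-stream seeds derived from the master seed.
.stream_seeds <- function(cfg) {
  set.seed(cfg$seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 9),
                  c("tads", "genes", "peaks", "repeats", "tracks",
                    "de", "sequence", "motif", "spectral"))
}

#' Simulate a TAD tiling
#'
#' Tiles each chromosome with TADs of uniform random length within the
#' configured range, inserting an inter-TAD gap with the configured
#' probability.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional sub-stream seed (derived from the master seed
#'   when omitted).
#' @return `GRanges` with `tad_id`.
#' @export
simulate_tads <- function(cfg, seed = NULL) {
  set.seed(if (is.null(seed)) .stream_seeds(cfg)[["tads"]] else seed)
  rows <- list()
  for (ch in names(cfg$chrom_lengths)) {
    L <- cfg$chrom_lengths[[ch]]
    pos <- 0
    while (TRUE) {
      if (stats::runif(1) < cfg$tad_gap_prob)
        pos <- pos + floor(stats::runif(1, cfg$tad_gap_range[1],
                                        cfg$tad_gap_range[2]))
      len <- floor(stats::runif(1, cfg$tad_length_range[1],
                                cfg$tad_length_range[2]))
      if (pos + len > L) break
      rows[[length(rows) + 1L]] <- data.frame(chrom = ch, start0 = pos,
                                              end0 = pos + len)
      pos <- pos + len
    }
  }
  df <- do.call(rbind, rows)
  gr <- GRanges(df$chrom, IRanges(df$start0 + 1, df$end0))
  mcols(gr)$tad_id <- sprintf("tad_%04d", seq_along(gr))
  gr
}

#' Simulate strand-aware genes
#' @inheritParams simulate_tads
#' @return `GRanges` with `gene_id` and strand.
#' @export
simulate_genes <- function(cfg, seed = NULL) {
  set.seed(if (is.null(seed)) .stream_seeds(cfg)[["genes"]] else seed)
  n <- cfg$n_genes
  chrs <- sample(names(cfg$chrom_lengths), n, replace = TRUE,
                 prob = as.numeric(cfg$chrom_lengths))
  len <- floor(stats::runif(n, cfg$gene_length_range[1],
                            cfg$gene_length_range[2]))
  lim <- as.numeric(cfg$chrom_lengths[chrs])
  start0 <- floor(stats::runif(n, 0, lim - len))
  gr <- GRanges(chrs, IRanges(start0 + 1, start0 + len))
  strand(gr) <- ifelse(stats::runif(n) < cfg$p_plus_strand, "+", "-")
  mcols(gr)$gene_id <- sprintf("gene_%04d", seq_len(n))
  gr
}

#' Simulate archetype-labelled peaks
#'
#' Peaks are placed (centre) inside TAD territory at the configured
#' rate, otherwise uniformly on the genome; summit = centre.
#'
#' @inheritParams simulate_tads
#' @param tads `GRanges` from [simulate_tads()].
#' @return `GRanges` with `name`, `summit`, `archetype`.
#' @export
simulate_peaks <- function(cfg, tads, seed = NULL) {
  set.seed(if (is.null(seed)) .stream_seeds(cfg)[["peaks"]] else seed)
  n_total <- sum(cfg$n_peaks)
  arch <- rep(seq_along(cfg$n_peaks), cfg$n_peaks)
  if (n_total == 0) {
    gr <- GRanges()
    mcols(gr)$name <- character(0)
    mcols(gr)$score <- numeric(0)
    mcols(gr)$summit <- integer(0)
    mcols(gr)$archetype <- integer(0)
    return(gr)
  }
  w <- floor(stats::runif(n_total, cfg$peak_width_range[1],
                          cfg$peak_width_range[2]))
  in_tad <- stats::runif(n_total) < cfg$peak_in_tad_rate & length(tads) > 0
  ctr0 <- numeric(n_total)
  chrs <- character(n_total)
  if (any(in_tad)) {
    ti <- sample.int(length(tads), sum(in_tad), replace = TRUE,
                     prob = as.numeric(width(tads)))
    ctr0[in_tad] <- start(tads)[ti] - 1 +
      floor(stats::runif(sum(in_tad)) * width(tads)[ti])
    chrs[in_tad] <- as.character(seqnames(tads))[ti]
  }
  if (any(!in_tad)) {
    m <- sum(!in_tad)
    ch <- sample(names(cfg$chrom_lengths), m, replace = TRUE,
                 prob = as.numeric(cfg$chrom_lengths))
    ctr0[!in_tad] <- floor(stats::runif(m) * as.numeric(cfg$chrom_lengths[ch]))
    chrs[!in_tad] <- ch
  }
  half <- w %/% 2
  lim <- as.numeric(cfg$chrom_lengths[chrs])
  s0 <- pmax(0, ctr0 - half)
  e0 <- pmin(lim, ctr0 + (w - half))
  gr <- GRanges(chrs, IRanges(s0 + 1, e0))
  mcols(gr)$name <- sprintf("peak_%04d", seq_len(n_total))
  mcols(gr)$score <- 0
  mcols(gr)$summit <- as.integer(ctr0 + 1)
  mcols(gr)$archetype <- arch
  gr
}

#' Simulate class-labelled repeat elements
#'
#' Conditioned placements put an element of the configured class/family
#' inside each peak of the matching archetype with the configured rate;
#' background elements of mixed classes are scattered uniformly.
#'
#' @inheritParams simulate_peaks
#' @param peaks `GRanges` from [simulate_peaks()].
#' @return `GRanges` with `repeat_name`, `repeat_class`,
#'   `repeat_family`.
#' @export
simulate_repeats <- function(cfg, peaks, seed = NULL) {
  set.seed(if (is.null(seed)) .stream_seeds(cfg)[["repeats"]] else seed)
  rows <- list()
  place_in_peak <- function(p_idx, fam, cls) {
    w <- floor(stats::runif(1, cfg$repeat_width_range[1],
                            cfg$repeat_width_range[2]))
    c0 <- peak_centre(peaks[p_idx]) - 1 +
      floor(stats::runif(1, -width(peaks[p_idx]) / 4, width(peaks[p_idx]) / 4))
    s0 <- max(0, c0 - w %/% 2)
    data.frame(chrom = as.character(seqnames(peaks[p_idx])),
               start0 = s0, end0 = s0 + w,
               strand = sample(c("+", "-"), 1),
               name = paste0(fam, "_elt"), class = cls, family = fam)
  }
  arch <- mcols(peaks)$archetype
  for (r in seq_len(nrow(cfg$repeat_rates))) {
    rr <- cfg$repeat_rates[r, ]
    for (i in which(arch == rr$archetype))
      if (stats::runif(1) < rr$rate)
        rows[[length(rows) + 1L]] <- place_in_peak(i, rr$family, rr$class)
  }
  # background elements anywhere on the genome
  bg_cls <- sample(c("LTR", "SINE", "LINE"), cfg$n_background_repeats,
                   replace = TRUE)
  bg_fam <- vapply(bg_cls, function(cl)
    sample(switch(cl, LTR = c("ERV1", "ERVK", "ERVL"),
                  SINE = c("Alu", "MIR"), LINE = c("L1", "L2")), 1),
    character(1))
  for (i in seq_len(cfg$n_background_repeats)) {
    ch <- sample(names(cfg$chrom_lengths), 1,
                 prob = as.numeric(cfg$chrom_lengths))
    w <- floor(stats::runif(1, cfg$repeat_width_range[1],
                            cfg$repeat_width_range[2]))
    s0 <- floor(stats::runif(1, 0, cfg$chrom_lengths[[ch]] - w))
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = ch, start0 = s0, end0 = s0 + w,
      strand = sample(c("+", "-"), 1),
      name = paste0(bg_fam[i], "_bg"), class = bg_cls[i], family = bg_fam[i])
  }
  df <- do.call(rbind, rows)
  gr <- GRanges(df$chrom, IRanges(df$start0 + 1, df$end0))
  strand(gr) <- df$strand
  mcols(gr)$repeat_name <- paste0(df$name, "_", seq_along(gr))
  mcols(gr)$repeat_class <- df$class
  mcols(gr)$repeat_family <- df$family
  gr
}

#' Simulate multi-track coverage around peaks
#'
#' Each peak contributes a Gaussian-shaped coverage bump per track whose
#' height is negative-binomial around the archetype's mean for that
#' track, on top of a constant background; signal is generated at
#' `track_bin` bp resolution.
#'
#' @inheritParams simulate_peaks
#' @param peaks `GRanges` with an `archetype` column.
#' @return Named list of `CoverageTrack` objects.
#' @export
simulate_tracks <- function(cfg, peaks, seed = NULL) {
  set.seed(if (is.null(seed)) .stream_seeds(cfg)[["tracks"]] else seed)
  bin <- cfg$track_bin
  arch <- mcols(peaks)$archetype
  ctr0 <- peak_centre(peaks) - 1L
  pchr <- as.character(seqnames(peaks))
  reach_bins <- ceiling(3 * cfg$bump_sd / bin)
  out <- list()
  for (t in seq_along(cfg$tracks)) {
    label <- cfg$tracks[t]
    covs <- list()
    heights <- stats::rnbinom(length(peaks), size = cfg$nb_size,
                              mu = cfg$archetype_means[arch, t])
    for (ch in names(cfg$chrom_lengths)) {
      L <- cfg$chrom_lengths[[ch]]
      nb <- ceiling(L / bin)
      v <- rep(cfg$background, nb)
      for (i in which(pchr == ch)) {
        cb <- ctr0[i] %/% bin + 1L
        idx <- max(1L, cb - reach_bins):min(nb, cb + reach_bins)
        x0 <- (idx - 1) * bin + bin / 2
        v[idx] <- v[idx] +
          heights[i] * exp(-(x0 - ctr0[i])^2 / (2 * cfg$bump_sd^2))
      }
      lens <- rep(bin, nb)
      lens[nb] <- L - (nb - 1) * bin   # truncate the final bin at chrom end
      covs[[ch]] <- Rle(v, lens)
    }
    out[[label]] <- coverage_track(methods::as(covs, "SimpleRleList"), label)
  }
  out
}

#' Simulate a DE statistics table with a planted regional effect
#'
#' Null genes get `log2FC ~ Normal(0, lfc_sd)`; a baseline fraction of
#' genes are genuinely regulated (half shifted up, half down by
#' `de_shift`); additionally `regional_frac` of the remaining null genes
#' whose TAD contains an archetype-1 peak are shifted up by
#' `regional_shift` — the planted regional repression signature.
#' P-values come from the z-score of the observed log2FC against the
#' known noise sd, with Benjamini-Hochberg adjustment across all genes
#' (no count-level simulation: the analysis consumes DE tables, not
#' reads).
#'
#' @inheritParams simulate_peaks
#' @param genes,tads,peaks Simulated annotation (peaks need
#'   `archetype`).
#' @return List with `table` (gene_id, log2_fold_change, p_value,
#'   adjusted_p) and `truth` (per-gene planted label: `up`, `down`,
#'   `regional_up`, `null`).
#' @export
simulate_de_table <- function(cfg, genes, tads, peaks, seed = NULL) {
  set.seed(if (is.null(seed)) .stream_seeds(cfg)[["de"]] else seed)
  n <- length(genes)
  mu <- numeric(n)
  truth <- rep("null", n)
  n_de <- floor(cfg$baseline_de_frac * n)
  de_idx <- sample.int(n, n_de)
  up_idx <- de_idx[seq_len(n_de %/% 2)]
  dn_idx <- base::setdiff(de_idx, up_idx)
  mu[up_idx] <- cfg$de_shift; truth[up_idx] <- "up"
  mu[dn_idx] <- -cfg$de_shift; truth[dn_idx] <- "down"
  if (cfg$regional_shift != 0 && cfg$regional_frac > 0 && length(peaks)) {
    asg <- assign_to_tads(peaks, genes, tads)
    c1_tads <- unique(asg$peak_tad[mcols(peaks)$archetype == 1])
    c1_tads <- c1_tads[!is.na(c1_tads)]
    eligible <- which(truth == "null" & !is.na(asg$gene_tad) &
                        asg$gene_tad %in% c1_tads)
    reg <- sample(eligible, floor(cfg$regional_frac * length(eligible)))
    mu[reg] <- mu[reg] + cfg$regional_shift
    truth[reg] <- "regional_up"
  }
  lfc <- mu + stats::rnorm(n, 0, cfg$lfc_sd)
  p <- 2 * stats::pnorm(-abs(lfc / cfg$lfc_sd))
  list(table = data.frame(gene_id = mcols(genes)$gene_id,
                          log2_fold_change = lfc,
                          p_value = p,
                          adjusted_p = stats::p.adjust(p, "BH")),
       truth = stats::setNames(truth, mcols(genes)$gene_id))
}

# Draw one concrete instantiation of an IUPAC motif.
.instantiate_motif <- function(motif) {
  amb <- list(A = "A", C = "C", G = "G", T = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))
  paste(vapply(strsplit(toupper(motif), "")[[1]],
               function(c) sample(amb[[c]], 1), character(1)), collapse = "")
}

#' Simulate a genome sequence with planted motifs
#'
#' Uniform random bases per chromosome; a concrete instantiation of the
#' configured IUPAC consensus is planted (on a random strand) at the
#' summit of each archetype-`motif_archetype` peak with probability
#' `motif_rate`.
#'
#' @inheritParams simulate_peaks
#' @param peaks `GRanges` with `archetype` and `summit`.
#' @return List with `sequences` (`DNAStringSet`) and `motif_truth`
#'   (data frame of planted peak, position, strand).
#' @export
simulate_genome_sequence <- function(cfg, peaks, seed = NULL) {
  seeds <- .stream_seeds(cfg)
  set.seed(if (is.null(seed)) seeds[["sequence"]] else seed)
  seqs <- lapply(names(cfg$chrom_lengths), function(ch)
    paste(sample(c("A", "C", "G", "T"), cfg$chrom_lengths[[ch]],
                 replace = TRUE), collapse = ""))
  names(seqs) <- names(cfg$chrom_lengths)
  set.seed(seeds[["motif"]])
  truth <- list()
  if (length(peaks)) {
    idx <- which(mcols(peaks)$archetype == cfg$motif_archetype)
    plant <- idx[stats::runif(length(idx)) < cfg$motif_rate]
    for (i in plant) {
      inst <- .instantiate_motif(cfg$motif)
      strand <- sample(c("+", "-"), 1)
      if (strand == "-")
        inst <- as.character(reverseComplement(DNAString(inst)))
      ch <- as.character(seqnames(peaks))[i]
      pos <- mcols(peaks)$summit[i]
      if (pos + nchar(inst) - 1 > cfg$chrom_lengths[[ch]]) next
      substr(seqs[[ch]], pos, pos + nchar(inst) - 1) <- inst
      truth[[length(truth) + 1L]] <- data.frame(
        peak = mcols(peaks)$name[i], chrom = ch, pos = pos, strand = strand)
    }
  }
  list(sequences = DNAStringSet(unlist(seqs)),
       motif_truth = if (length(truth)) do.call(rbind, truth)
                     else data.frame(peak = character(0), chrom = character(0),
                                     pos = integer(0), strand = character(0)))
}

#' Simulate a spectral-count table
#'
#' True interactors (consistent non-zero counts above the keep
#' threshold), frequent-contaminant proteins, ribosomal proteins and
#' dropout proteins (a zero count in one experiment) with the
#' category recorded as truth.
#'
#' @inheritParams simulate_tads
#' @return List with `table` and `truth` (named category vector).
#' @export
simulate_spectral_counts <- function(cfg, seed = NULL) {
  set.seed(if (is.null(seed)) .stream_seeds(cfg)[["spectral"]] else seed)
  ne <- cfg$n_experiments
  mk <- function(n, prefix, mu, crap, ribo) {
    counts <- matrix(stats::rnbinom(n * ne, size = 10, mu = mu), ncol = ne)
    data.frame(protein_id = sprintf("%s%02d", prefix, seq_len(n)),
               counts, crapome_frequency = crap,
               is_ribosomal = ribo)
  }
  true <- mk(cfg$n_true_interactors, "INT", cfg$true_count_mean,
             stats::runif(cfg$n_true_interactors, 0, 0.3), FALSE)
  true[, 2:(1 + ne)] <- true[, 2:(1 + ne)] + 5L  # keep clear of zero/threshold
  crap <- mk(cfg$n_contaminants, "CRP", cfg$contaminant_count_mean,
             stats::runif(cfg$n_contaminants, 0.55, 1), FALSE)
  ribo <- mk(cfg$n_ribosomal, "RPL", cfg$true_count_mean,
             stats::runif(cfg$n_ribosomal, 0, 0.3), TRUE)
  drop <- mk(cfg$n_dropout, "DRP", cfg$true_count_mean,
             stats::runif(cfg$n_dropout, 0, 0.3), FALSE)
  for (i in seq_len(cfg$n_dropout))
    drop[i, 1 + sample.int(ne, 1)] <- 0L
  tab <- rbind(true, crap, ribo, drop)
  names(tab)[2:(1 + ne)] <- sprintf("experiment_%d", seq_len(ne))
  truth <- stats::setNames(rep(c("true", "contaminant", "ribosomal", "dropout"),
                               c(cfg$n_true_interactors, cfg$n_contaminants,
                                 cfg$n_ribosomal, cfg$n_dropout)),
                           tab$protein_id)
  list(table = tab, truth = truth)
}

#' Simulate a complete dataset bundle
#'
#' Orchestrates every sub-generator under named seed sub-streams into an
#' internally consistent bundle (shared chromosome names and lengths,
#' all intervals in bounds), optionally written to disk in the standard
#' formats: `genome.fa`, `genes.tsv`, `tads.bed`, `repeats.tsv`,
#' `peaks.narrowPeak`, `tracks/<label>.bedGraph`, `de.tsv`,
#' `spectral_counts.tsv`, plus truth tables
#' (`truth_peak_archetypes.tsv`, `truth_gene_labels.tsv`,
#' `truth_motif.tsv`).
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created); `NULL` keeps the bundle in
#'   memory only.
#' @param components Subset of
#'   `c("tads","genes","peaks","repeats","tracks","de","sequence","spectral")`
#'   to generate (annotation stages needed by a requested stage are
#'   always generated).
#' @return The bundle list (invisibly when written to disk).
#' @export
simulate_bundle <- function(cfg, out_dir = NULL,
                            components = c("tads", "genes", "peaks",
                                           "repeats", "tracks", "de",
                                           "sequence", "spectral")) {
  stopifnot(inherits(cfg, "sim_config"))
  seeds <- .stream_seeds(cfg)
  b <- list(config = cfg, chrom_lengths = cfg$chrom_lengths)
  b$tads <- simulate_tads(cfg, seeds[["tads"]])
  b$genes <- simulate_genes(cfg, seeds[["genes"]])
  b$peaks <- simulate_peaks(cfg, b$tads, seeds[["peaks"]])
  if ("repeats" %in% components)
    b$repeats <- simulate_repeats(cfg, b$peaks, seeds[["repeats"]])
  if ("tracks" %in% components)
    b$tracks <- simulate_tracks(cfg, b$peaks, seeds[["tracks"]])
  if ("de" %in% components) {
    de <- simulate_de_table(cfg, b$genes, b$tads, b$peaks, seeds[["de"]])
    b$de <- de$table
    b$truth_gene <- de$truth
  }
  if ("sequence" %in% components) {
    sq <- simulate_genome_sequence(cfg, b$peaks)
    b$sequences <- sq$sequences
    b$truth_motif <- sq$motif_truth
  }
  if ("spectral" %in% components) {
    sp <- simulate_spectral_counts(cfg, seeds[["spectral"]])
    b$spectral <- sp$table
    b$truth_spectral <- sp$truth
  }
  b$truth_archetype <- stats::setNames(mcols(b$peaks)$archetype,
                                       mcols(b$peaks)$name)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_intervals(b$tads, file.path(out_dir, "tads.bed"), "tad_bed")
    write_intervals(b$genes, file.path(out_dir, "genes.tsv"), "gene_tsv")
    write_intervals(b$peaks, file.path(out_dir, "peaks.narrowPeak"),
                    "narrowPeak")
    if (!is.null(b$repeats))
      write_intervals(b$repeats, file.path(out_dir, "repeats.tsv"),
                      "repeat_tsv")
    if (!is.null(b$tracks)) {
      dir.create(file.path(out_dir, "tracks"), showWarnings = FALSE)
      for (tr in b$tracks)
        write_bedgraph(tr, file.path(out_dir, "tracks",
                                     paste0(tr$label, ".bedGraph")))
    }
    if (!is.null(b$de)) {
      utils::write.table(b$de, file.path(out_dir, "de.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(gene_id = names(b$truth_gene), label = b$truth_gene),
        file.path(out_dir, "truth_gene_labels.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(b$sequences)) {
      writeXStringSet(b$sequences, file.path(out_dir, "genome.fa"))
      utils::write.table(b$truth_motif, file.path(out_dir, "truth_motif.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(b$spectral))
      utils::write.table(b$spectral,
                         file.path(out_dir, "spectral_counts.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(peak = names(b$truth_archetype),
                 archetype = b$truth_archetype),
      file.path(out_dir, "truth_peak_archetypes.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(b))
  }
  b
}
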
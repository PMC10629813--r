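#' Default pipeline parameters
#'
#' Stage parameters with defaults matching the analysis conventions the
#' package implements: 10 kb signal window with 100 bins, k = 3
#' clusters, mutual-overlap fraction 0.3, DE thresholds fold change 1.6
#' and adjusted p 0.01, distance brackets 5/10/25/50/100 kb, 10 random
#' control gene sets, 1000 permutations, +/-25% mirror tolerance, and
#' 2 control sets of 2360 boundary-distance positions.
#'
#' @return Named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(window = 10000, n_bins = 100, k = 3, seed = 1L, n_init = 25,
       overlap_frac = 0.3,
       fold_change = 1.6, alpha = 0.01,
       brackets = c(5000, 10000, 25000, 50000, 100000),
       n_control_gene_sets = 10,
       n_perm = 1000,
       mirror_tolerance = 0.25,
       n_boundary_controls = 2360, n_boundary_control_sets = 2,
       motif = "CGCCCYCTNSTG", motif_window = 101,
       repressive_track = NULL, active_track = NULL,
       crapome_max = 0.5, min_avg_count = 4)
}

.read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  params <- utils::modifyList(pipeline_defaults(),
                              if (is.null(config$params)) list()
                              else config$params)
  list(inputs = config$inputs, params = params)
}

.stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order on file inputs —
#' cluster (signal matrix + k-means + profiles), annotate (genomic
#' distribution), repeats (class and LTR-family composition), motif
#' (consensus frequency vs random background, when a FASTA is given),
#' associate (DE calls, directional overlap, distance brackets with
#' random-gene controls) and tad (directional proportions,
#' co-localization permutation, boundary distances, adjacent-TAD
#' mirror) — writing per-stage TSVs, a JSON run manifest (parameter
#' values, seed, input checksums, per-stage row counts) and a
#' human-readable summary. Inputs are validated before any stage runs;
#' a stage failure aborts with the stage named.
#'
#' @param config Path to a YAML file or a list, with `inputs` (paths:
#'   `peaks`, `tracks` named list, `genes`, `tads`, `repeats`, `de`,
#'   optional `fasta`, optional `spectral`) and optional `params`
#'   overriding [pipeline_defaults()].
#' @param out_dir Output directory.
#' @return List of stage results (invisibly); outputs on disk.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- .read_run_config(config)
  inp <- cfg$inputs
  p <- cfg$params
  req <- c("peaks", "tracks", "genes", "tads", "de")
  miss <- base::setdiff(req, names(inp))
  if (length(miss))
    stop("missing input(s): ", paste(miss, collapse = ", "))
  paths <- c(unlist(inp[base::setdiff(names(inp), "tracks")]),
             unlist(inp$tracks))
  absent <- paths[!file.exists(paths)]
  if (length(absent))
    stop("input file(s) not found: ", paste(absent, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  counts <- list()
  wtsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    counts[[name]] <<- nrow(df)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  run_stage("cluster", {
    peaks <- read_intervals(inp$peaks, "narrowPeak")
    tracks <- lapply(names(inp$tracks), function(nm)
      read_bedgraph(inp$tracks[[nm]], nm))
    mat <- compute_signal_matrix(peaks, tracks, p$window, p$n_bins)
    asg <- cluster_peaks(mat, k = p$k, seed = p$seed, n_init = p$n_init,
                         repressive_track = p$repressive_track,
                         active_track = p$active_track)
    prof <- cluster_profiles(mat, asg)
    wtsv(data.frame(peak = names(asg$labels), cluster = asg$labels),
         "cluster_assignments.tsv")
    wtsv(prof, "cluster_profiles.tsv")
    .stage_log("cluster", "%d peaks -> k = %d clusters (sizes %s)",
               length(peaks), asg$k, paste(asg$sizes, collapse = "/"))
    res$peaks <- peaks; res$assignment <- asg; res$matrix <- mat
  })

  genes <- read_intervals(inp$genes, "gene_tsv")
  tads <- read_intervals(inp$tads, "tad_bed")

  run_stage("annotate", {
    cls <- classify_summits(res$peaks, genes)
    wtsv(data.frame(peak = mcols(res$peaks)$name, category = cls),
         "peak_categories.tsv")
    lab <- res$assignment$labels[mcols(res$peaks)$name]
    tab <- do.call(rbind, lapply(sort(unique(lab)), function(c)
      data.frame(cluster = c,
                 category = levels(cls),
                 proportion = as.numeric(table(cls[lab == c])) /
                   max(1, sum(lab == c)))))
    wtsv(tab, "genomic_distribution.tsv")
    .stage_log("annotate", "%d peaks classified into %d categories",
               length(cls), nlevels(cls))
    res$categories <- cls
  })

  if (!is.null(inp$repeats)) run_stage("repeats", {
    reps <- read_intervals(inp$repeats, "repeat_tsv")
    lab <- res$assignment$labels[mcols(res$peaks)$name]
    comp <- repeat_composition(res$peaks, unname(lab), reps, "class")
    fam <- repeat_composition(res$peaks, unname(lab), reps, "family",
                              parent_class = "LTR")
    wtsv(comp, "repeat_class_composition.tsv")
    wtsv(fam, "repeat_ltr_family_composition.tsv")
    .stage_log("repeats", "%d repeat elements profiled", length(reps))
    res$repeat_composition <- comp
  })

  if (!is.null(inp$fasta)) run_stage("motif", {
    seqs <- readDNAStringSet(inp$fasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    scan <- consensus_scan(res$peaks, seqs, p$motif, p$motif_window)
    lens <- stats::setNames(Biostrings::width(seqs), names(seqs))
    bg_regions <- random_background_regions(res$peaks, lens, times = 10,
                                            seed = p$seed)
    bg <- consensus_scan(bg_regions, seqs, p$motif, p$motif_window)
    wtsv(scan$hits, "motif_hits.tsv")
    wtsv(data.frame(set = c("peaks", "background"),
                    n = c(scan$n_regions, bg$n_regions),
                    n_hit = c(scan$n_hit, bg$n_hit),
                    fraction = c(scan$fraction, bg$fraction)),
         "motif_summary.tsv")
    .stage_log("motif", "%d/%d peaks match %s (background %.3f)",
               scan$n_hit, scan$n_regions, p$motif, bg$fraction)
    res$motif <- list(peaks = scan, background = bg)
  })

  de <- run_stage("associate", {
    de <- call_de(utils::read.delim(inp$de), p$fold_change, p$alpha)
    up <- de$gene_id[de$label == "up"]
    down <- de$gene_id[de$label == "down"]
    universe <- genes[mcols(genes)$gene_id %in% de$gene_id]
    assoc_up <- distance_bracket_association(res$peaks, up, universe,
                                             p$brackets)
    assoc_down <- distance_bracket_association(res$peaks, down, universe,
                                               p$brackets)
    ctrl <- random_gene_control(res$peaks, max(1, length(up)), universe,
                                p$brackets, p$n_control_gene_sets, p$seed)
    assoc_up$set <- "up"; assoc_down$set <- "down"
    wtsv(rbind(assoc_up, assoc_down), "distance_bracket_association.tsv")
    wtsv(ctrl, "random_gene_control.tsv")
    wtsv(de[, c("gene_id", "log2_fold_change", "adjusted_p", "label")],
         "de_calls.tsv")
    .stage_log("associate", "%d up / %d down of %d genes",
               length(up), length(down), nrow(de))
    res$de <- de; res$up <- up; res$down <- down
    res$universe <- universe
    de
  })

  run_stage("tad", {
    asg <- assign_to_tads(res$peaks, res$universe, tads)
    lab <- res$assignment$labels
    dir_prop <- tad_direction_proportions(asg, lab, res$up, res$down)
    cl1 <- names(lab)[lab == 1]
    coloc <- colocalization_permutation_test(res$up, asg, peak_ids = cl1,
                                             n_perm = p$n_perm,
                                             seed = p$seed)
    bdist <- boundary_distance_test(asg, lab, p$n_boundary_controls,
                                    p$n_boundary_control_sets, p$seed)
    mirror <- adjacent_tad_mirror(asg, res$up, p$mirror_tolerance)
    wtsv(dir_prop, "tad_direction_proportions.tsv")
    wtsv(data.frame(
      metric = c("coloc_observed", "coloc_p",
                 "mirror_peaks", "mirror_genes", "mirror_up"),
      value = c(coloc$observed, coloc$p, mirror$n_qualifying_peaks,
                mirror$n_candidate_genes, mirror$n_up_candidates)),
         "tad_summary.tsv")
    bd <- do.call(rbind, c(
      lapply(names(bdist$cluster_distances), function(n)
        data.frame(set = paste0("cluster_", n),
                   distance = bdist$cluster_distances[[n]])),
      lapply(seq_along(bdist$control_distances), function(i)
        data.frame(set = paste0("control_", i),
                   distance = bdist$control_distances[[i]]))))
    wtsv(bd, "boundary_distances.tsv")
    .stage_log("tad", "coloc p = %.4g; mirror %d peaks / %d genes / %d up",
               coloc$p, mirror$n_qualifying_peaks, mirror$n_candidate_genes,
               mirror$n_up_candidates)
    res$tad <- list(direction = dir_prop, coloc = coloc,
                     boundary = bdist, mirror = mirror)
  })

  if (!is.null(inp$spectral)) run_stage("rime", {
    sp <- read_spectral_counts(inp$spectral)
    kept <- filter_interactors(sp, p$crapome_max, p$min_avg_count)
    wtsv(kept, "rime_interactors.tsv")
    .stage_log("rime", "%d of %d proteins kept", nrow(kept), nrow(sp))
    res$rime <- kept
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("tadreg")),
    parameters = p,
    inputs = as.list(paths),
    input_md5 = as.list(tools::md5sum(paths)),
    output_row_counts = counts,
    stages = names(counts))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  summary_lines <- c(
    sprintf("tadreg pipeline (seed %d)", p$seed),
    sprintf("peaks: %d in %d clusters (sizes %s)", length(res$peaks),
            res$assignment$k, paste(res$assignment$sizes, collapse = "/")),
    sprintf("DE genes: %d up, %d down of %d", length(res$up),
            length(res$down), nrow(res$de)),
    sprintf("TAD co-localization p = %.4g", res$tad$coloc$p),
    sprintf("mirror control: %d peaks, %d genes, %d up",
            res$tad$mirror$n_qualifying_peaks,
            res$tad$mirror$n_candidate_genes,
            res$tad$mirror$n_up_candidates))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  invisible(res)
}
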
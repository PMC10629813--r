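#' Assign peaks and genes to TADs
#'
#' Containment is by peak centre and gene TSS within the half-open TAD
#' interval: a position exactly at a TAD start belongs to it, a position
#' at the (exclusive) end does not. TADs must be non-overlapping per
#' chromosome, so each item lands in at most one TAD; items outside
#' every TAD are recorded as unassigned.
#'
#' @param peaks `GRanges` with a `name` column (generated when absent).
#' @param genes Stranded `GRanges` with `gene_id`.
#' @param tads `GRanges` with `tad_id` (validated with
#'   [validate_tads()]).
#' @return A `TADAssignment`: list with `peaks`, `genes`, `tads`,
#'   `peak_tad` and `gene_tad` (named character vectors, `NA` =
#'   unassigned) plus `unassigned_peaks` / `unassigned_genes`.
#' @export
assign_to_tads <- function(peaks, genes, tads) {
  validate_tads(tads)
  tid <- mcols(tads)$tad_id
  if (is.null(tid)) tid <- sprintf("tad_%04d", seq_along(tads))
  pids <- mcols(peaks)$name
  if (is.null(pids)) pids <- sprintf("peak_%d", seq_along(peaks))
  gids <- mcols(genes)$gene_id
  contain <- function(chr, pos) {
    gr <- GRanges(chr, IRanges(pos, width = 1L))
    hits <- findOverlaps(gr, tads)
    out <- rep(NA_character_, length(gr))
    out[queryHits(hits)] <- tid[subjectHits(hits)]
    out
  }
  peak_tad <- stats::setNames(
    contain(as.character(seqnames(peaks)), peak_centre(peaks)), pids)
  gene_tad <- stats::setNames(
    contain(as.character(seqnames(genes)), gene_tss(genes)), gids)
  structure(list(peaks = peaks, genes = genes, tads = tads,
                 peak_tad = peak_tad, gene_tad = gene_tad,
                 unassigned_peaks = pids[is.na(peak_tad)],
                 unassigned_genes = gids[is.na(gene_tad)]),
            class = "TADAssignment")
}

#' @export
print.TADAssignment <- function(x, ...) {
  cat(sprintf("TADAssignment: %d TADs; %d/%d peaks and %d/%d genes assigned\n",
              length(x$tads),
              sum(!is.na(x$peak_tad)), length(x$peak_tad),
              sum(!is.na(x$gene_tad)), length(x$gene_tad)))
  invisible(x)
}

# TAD ids containing at least one of the given peaks.
.peak_tads <- function(assignment, peak_ids = NULL) {
  pt <- assignment$peak_tad
  if (!is.null(peak_ids)) pt <- pt[names(pt) %in% peak_ids]
  unique(pt[!is.na(pt)])
}

#' Directional expression proportions per TAD category
#'
#' Groups TADs by their peak-cluster content (a TAD belongs to category
#' "cluster c" when it contains at least one cluster-c peak; with
#' `multiple = "inclusive"`, the default, a TAD with peaks from several
#' clusters counts in each such category; `"exclusive"` drops such TADs
#' from the cluster categories). Genes are counted through their TAD:
#' for each category the up and down counts, the proportion up, and a
#' two-sided Fisher exact test of (up, down) against the no-peak
#' category. Gene-level counting pseudoreplicates genes within a TAD;
#' this is deliberate and documented.
#'
#' @param assignment A `TADAssignment`.
#' @param peak_clusters Named vector (peak id -> cluster label) or a
#'   `ClusterAssignment`.
#' @param up,down Disjoint character vectors of gene ids.
#' @param multiple `"inclusive"` or `"exclusive"`.
#' @return Data frame: `category`, `n_tads`, `up`, `down`, `prop_up`,
#'   `fisher_p` (`NA` for the no-peak row itself, and wherever a
#'   comparison is undefined).
#' @export
tad_direction_proportions <- function(assignment, peak_clusters, up, down,
                                      multiple = c("inclusive", "exclusive")) {
  multiple <- match.arg(multiple)
  if (length(base::intersect(up, down)))
    stop("up and down gene sets must be disjoint")
  if (inherits(peak_clusters, "ClusterAssignment"))
    peak_clusters <- peak_clusters$labels
  pt <- assignment$peak_tad
  common <- base::intersect(names(pt), names(peak_clusters))
  pt <- pt[common]; cl <- peak_clusters[common]
  gt <- assignment$gene_tad
  labs <- sort(unique(cl))
  tads_by_cluster <- lapply(labs, function(c) unique(pt[!is.na(pt) & cl == c]))
  names(tads_by_cluster) <- as.character(labs)
  if (multiple == "exclusive") {
    n_cl <- vapply(unique(pt[!is.na(pt)]), function(t)
      length(unique(cl[!is.na(pt) & pt == t])), numeric(1))
    multi <- names(n_cl)[n_cl > 1]
    tads_by_cluster <- lapply(tads_by_cluster, base::setdiff, multi)
  }
  no_peak <- base::setdiff(mcols(assignment$tads)$tad_id, unique(pt[!is.na(pt)]))
  count_cat <- function(tset) {
    genes_in <- names(gt)[!is.na(gt) & gt %in% tset]
    c(up = length(base::intersect(genes_in, up)),
      down = length(base::intersect(genes_in, down)))
  }
  np <- count_cat(no_peak)
  rows <- lapply(seq_along(labs), function(i) {
    cc <- count_cat(tads_by_cluster[[i]])
    p <- if (!length(no_peak) || sum(cc) == 0 || sum(np) == 0) NA_real_
         else stats::fisher.test(matrix(c(cc["up"], cc["down"],
                                          np["up"], np["down"]), 2))$p.value
    data.frame(category = paste0("cluster_", labs[i]),
               n_tads = length(tads_by_cluster[[i]]),
               up = cc[["up"]], down = cc[["down"]],
               prop_up = if (sum(cc) > 0) cc[["up"]] / sum(cc) else NA_real_,
               fisher_p = p)
  })
  rows[[length(rows) + 1L]] <- data.frame(
    category = "no_peak", n_tads = length(no_peak),
    up = np[["up"]], down = np[["down"]],
    prop_up = if (sum(np) > 0) np[["up"]] / sum(np) else NA_real_,
    fisher_p = NA_real_)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Co-localization of regulated genes with peak-bearing TADs
#'
#' Observed statistic: the fraction of (TAD-assigned) `up_genes` whose
#' TAD contains at least one peak (optionally restricted to given peak
#' ids, e.g. one cluster). The null permutes gene labels over all
#' assigned genes, preserving the genes-per-TAD structure; the empirical
#' p uses the add-one estimator `(1 + #{null >= obs}) / (1 + n_perm)`,
#' which never returns 0.
#'
#' @param up_genes Character vector of gene ids.
#' @param assignment A `TADAssignment`.
#' @param peak_ids Optional peak-id filter.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed.
#' @return List with `observed`, `p`, `null_mean`, `n_genes_used`.
#' @export
colocalization_permutation_test <- function(up_genes, assignment,
                                            peak_ids = NULL,
                                            n_perm = 1000, seed = 1L) {
  stopifnot(n_perm >= 1)
  ptads <- .peak_tads(assignment, peak_ids)
  gt <- assignment$gene_tad
  assigned <- names(gt)[!is.na(gt)]
  in_ptad <- stats::setNames(gt[assigned] %in% ptads, assigned)
  m <- sum(assigned %in% up_genes)
  if (m == 0 || !length(ptads))
    return(list(observed = 0, p = 1, null_mean = 0, n_genes_used = m))
  observed <- mean(in_ptad[assigned %in% up_genes])
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i)
    mean(in_ptad[sample(assigned, m)]), numeric(1))
  list(observed = observed,
       p = (1 + sum(null >= observed)) / (1 + n_perm),
       null_mean = mean(null),
       n_genes_used = m)
}

#' Peak-to-TAD-boundary distance test
#'
#' Distance of each assigned peak centre to the nearer of its TAD's two
#' boundaries, per cluster, compared with seeded control sets of uniform
#' positions within TAD-covered territory (controls are points, since
#' distances are measured from peak centres). Two-sided
#' unequal-variance t-tests per (cluster, control set). Distances never
#' exceed half the containing TAD's length.
#'
#' @param assignment A `TADAssignment`.
#' @param peak_clusters Named vector (peak id -> cluster) or
#'   `ClusterAssignment`.
#' @param n_control Control positions per set (default 2360).
#' @param n_control_sets Number of control sets (default 2).
#' @param seed Seed.
#' @return List with `cluster_distances` (list per cluster),
#'   `control_distances` (list per set), `p_values` (cluster x control
#'   matrix, `NA` when a cluster has fewer than 2 assigned peaks) and
#'   `n_unassigned`.
#' @export
boundary_distance_test <- function(assignment, peak_clusters,
                                   n_control = 2360, n_control_sets = 2,
                                   seed = 1L) {
  if (inherits(peak_clusters, "ClusterAssignment"))
    peak_clusters <- peak_clusters$labels
  tads <- assignment$tads
  tid <- mcols(tads)$tad_id
  s0 <- start(tads) - 1L; e0 <- end(tads)
  pt <- assignment$peak_tad
  pids <- names(pt)[!is.na(pt)]
  ctr0 <- peak_centre(assignment$peaks) - 1L
  names(ctr0) <- names(assignment$peak_tad)
  bdist <- function(c0, ti) pmin(c0 - s0[ti], e0[ti] - c0)
  labs <- sort(unique(peak_clusters[pids]))
  cluster_distances <- lapply(labs, function(cl) {
    ids <- pids[peak_clusters[pids] == cl]
    ti <- match(pt[ids], tid)
    unname(bdist(ctr0[ids], ti))
  })
  names(cluster_distances) <- as.character(labs)
  set.seed(seed)
  widths <- as.numeric(width(tads))
  control_distances <- lapply(seq_len(n_control_sets), function(i) {
    ti <- sample.int(length(tads), n_control, replace = TRUE, prob = widths)
    u0 <- s0[ti] + floor(stats::runif(n_control) * widths[ti])
    unname(bdist(u0, ti))
  })
  p <- matrix(NA_real_, length(labs), n_control_sets,
              dimnames = list(paste0("cluster_", labs),
                              paste0("control_", seq_len(n_control_sets))))
  for (i in seq_along(labs))
    for (j in seq_len(n_control_sets))
      if (length(cluster_distances[[i]]) >= 2)
        p[i, j] <- stats::t.test(cluster_distances[[i]],
                                 control_distances[[j]])$p.value
  list(cluster_distances = cluster_distances,
       control_distances = control_distances,
       p_values = p,
       n_unassigned = sum(is.na(pt)))
}

#' Adjacent-TAD distance-mirror control
#'
#' For every (peak, up-regulated gene) pair sharing a TAD, takes the
#' peak-to-TSS distance `d` and searches the opposite direction from the
#' peak for gene TSSs at a similar distance (within `tolerance`, default
#' +/-25%) that reside in a TAD different from the peak's own
#' (`mode = "any_other"`; `"flanking"` restricts to the immediately
#' neighbouring TAD on that chromosome). Reports how many peaks have at
#' least one such candidate, the number of unique candidate genes across
#' all qualifying peaks, and how many candidates are themselves
#' up-regulated — a test of whether transcriptional deregulation simply
#' spreads with distance across TAD boundaries.
#'
#' @param assignment A `TADAssignment`.
#' @param up_genes Character vector of up-regulated gene ids.
#' @param tolerance Relative distance tolerance in (0, 1), default 0.25.
#' @param mode `"any_other"` (default) or `"flanking"`.
#' @return List with `n_qualifying_peaks`, `n_candidate_genes`,
#'   `n_up_candidates` and the `candidates` id vector.
#' @export
adjacent_tad_mirror <- function(assignment, up_genes, tolerance = 0.25,
                                mode = c("any_other", "flanking")) {
  mode <- match.arg(mode)
  stopifnot(tolerance > 0, tolerance < 1)
  pt <- assignment$peak_tad
  gt <- assignment$gene_tad
  genes <- assignment$genes
  gids <- mcols(genes)$gene_id
  tss <- gene_tss(genes)
  gchr <- as.character(seqnames(genes))
  peaks <- assignment$peaks
  ctr <- peak_centre(peaks)
  pchr <- as.character(seqnames(peaks))
  tads <- assignment$tads
  tid <- mcols(tads)$tad_id
  flank_ok <- function(peak_tad_id, cand_tad_ids, ch) {
    idx <- which(as.character(seqnames(tads)) == ch)
    ord <- idx[order(start(tads)[idx])]
    pos <- match(peak_tad_id, tid[ord])
    neigh <- tid[ord][c(pos - 1, pos + 1)]
    cand_tad_ids %in% neigh[!is.na(neigh)]
  }
  qual_peaks <- character(0)
  cands <- character(0)
  for (i in seq_along(peaks)) {
    ptad <- pt[i]
    if (is.na(ptad)) next
    same_tad_up <- which(gids %in% up_genes & !is.na(gt) & gt == ptad)
    if (!length(same_tad_up)) next
    found <- FALSE
    for (g in same_tad_up) {
      d <- abs(tss[g] - ctr[i])
      if (d == 0) next
      s <- sign(tss[g] - ctr[i])
      lo <- ctr[i] - s * (1 + tolerance) * d
      hi <- ctr[i] - s * (1 - tolerance) * d
      win <- sort(c(lo, hi))
      hit <- which(gchr == pchr[i] & tss >= win[1] & tss <= win[2] &
                     !is.na(gt[gids]) & gt[gids] != ptad)
      if (mode == "flanking" && length(hit))
        hit <- hit[flank_ok(ptad, gt[gids[hit]], pchr[i])]
      if (length(hit)) {
        found <- TRUE
        cands <- c(cands, gids[hit])
      }
    }
    if (found) qual_peaks <- c(qual_peaks, names(pt)[i])
  }
  cands <- unique(cands)
  list(n_qualifying_peaks = length(qual_peaks),
       n_candidate_genes = length(cands),
       n_up_candidates = sum(cands %in% up_genes),
       candidates = cands)
}
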
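mk_tads <- function(starts0, ends0, chrom = "chr1")
  gr0(chrom, starts0, ends0, tad_id = sprintf("T%d", seq_along(starts0)))

test_that("TAD containment is half-open by centre and TSS", {
  tads <- mk_tads(c(0, 10000, 30000), c(10000, 20000, 40000))
  # TSS exactly at a TAD start belongs to it; at a TAD end it does not;
  # a gene in the inter-TAD gap is unassigned
  genes <- genes0("chr1", c(10000, 9999, 25000), c(15000, 19000, 26000),
                  c("+", "+", "+"), ids = c("at_start", "at_end", "gap"))
  # peak in a gap is unassigned
  peaks <- gr0("chr1", c(500, 22000), c(700, 22400), name = c("in1", "gapped"))
  asg <- assign_to_tads(peaks, genes, tads)
  expect_equal(unname(asg$gene_tad["at_start"]), "T2")
  expect_equal(unname(asg$gene_tad["at_end"]), "T1")  # last base of T1
  expect_equal(unname(asg$peak_tad["in1"]), "T1")
  expect_true(is.na(asg$peak_tad["gapped"]))
  expect_equal(asg$unassigned_genes, "gap")
  # partition: assigned + unassigned = totals
  expect_equal(sum(!is.na(asg$peak_tad)) + length(asg$unassigned_peaks),
               length(peaks))
  expect_error(assign_to_tads(peaks, genes,
                              mk_tads(c(0, 5000), c(10000, 15000))),
               "overlapping")
})

test_that("direction proportions and Fisher tests per TAD category", {
  tads <- mk_tads(seq(0, 90000, 10000), seq(10000, 100000, 10000))
  # cluster-1 peaks in T1..T3; no peaks in T4..T10
  peaks <- gr0("chr1", c(500, 10500, 20500), c(900, 10900, 20900),
               name = c("p1", "p2", "p3"))
  cl <- c(p1 = 1L, p2 = 1L, p3 = 1L)
  # 3 up genes in peak TADs; 3 down genes in no-peak TADs
  pos0 <- c(600, 11000, 21000, 30500, 40500, 50500)
  genes <- genes0("chr1", pos0, pos0 + 800, rep("+", 6),
                  ids = sprintf("g%d", 1:6))
  asg <- assign_to_tads(peaks, genes, tads)
  up <- c("g1", "g2", "g3"); down <- c("g4", "g5", "g6")
  dp <- tad_direction_proportions(asg, cl, up, down)
  c1 <- dp[dp$category == "cluster_1", ]
  expect_equal(c(c1$up, c1$down), c(3, 0))
  expect_equal(c1$prop_up, 1)
  # margins 3/3 over 6: two-sided Fisher p = 0.1
  expect_equal(c1$fisher_p, 0.1, tolerance = 1e-9)
  np <- dp[dp$category == "no_peak", ]
  expect_equal(c(np$up, np$down), c(0, 3))

  # identical up/down counts everywhere -> proportions 0.5, p = 1
  dp2 <- tad_direction_proportions(asg, cl, c("g1", "g4"), c("g2", "g5"))
  expect_true(all(dp2$prop_up == 0.5))
  expect_equal(dp2$fisher_p[dp2$category == "cluster_1"], 1)

  # no up or down genes -> proportion sentinel
  dp3 <- tad_direction_proportions(asg, cl, character(0), character(0))
  expect_true(all(is.na(dp3$prop_up)))

  expect_error(tad_direction_proportions(asg, cl, up, c("g1")), "disjoint")
})

test_that("multi-cluster TADs count inclusively or exclusively on demand", {
  tads <- mk_tads(c(0, 10000), c(10000, 20000))
  peaks <- gr0("chr1", c(500, 600, 10500), c(900, 1000, 10900),
               name = c("a", "b", "c"))
  cl <- c(a = 1L, b = 2L, c = 2L)
  g <- genes0("chr1", c(700, 10700), c(1500, 11500), c("+", "+"),
              ids = c("gA", "gB"))
  asg <- assign_to_tads(peaks, g, tads)
  inc <- tad_direction_proportions(asg, cl, "gA", "gB")
  expect_equal(inc$n_tads[inc$category == "cluster_1"], 1)
  expect_equal(inc$n_tads[inc$category == "cluster_2"], 2)
  exc <- tad_direction_proportions(asg, cl, "gA", "gB", multiple = "exclusive")
  expect_equal(exc$n_tads[exc$category == "cluster_1"], 0)
  expect_equal(exc$n_tads[exc$category == "cluster_2"], 1)
})

test_that("co-localization permutation test is seeded and calibrated", {
  tads <- mk_tads(seq(0, 190000, 10000), seq(10000, 200000, 10000))
  # peaks in the first 5 TADs
  pk0 <- seq(500, 40500, 10000)
  peaks <- gr0("chr1", pk0, pk0 + 400, name = sprintf("p%d", 1:5))
  # genes: 10 in peak TADs (all "up"), 30 elsewhere
  gin0 <- rep(seq(1000, 41000, 10000), 2)
  gout0 <- seq(52000, 197000, 5000)
  g <- genes0("chr1", c(gin0, gout0), c(gin0, gout0) + 500,
              rep("+", length(gin0) + length(gout0)))
  ids <- mcols(g)$gene_id
  asg <- assign_to_tads(peaks, g, tads)
  up <- ids[seq_along(gin0)]
  res <- colocalization_permutation_test(up, asg, n_perm = 1000, seed = 3)
  expect_equal(res$observed, 1)
  expect_lte(res$p, 0.01)
  expect_gt(res$p, 0)
  res2 <- colocalization_permutation_test(up, asg, n_perm = 1000, seed = 3)
  expect_identical(res$p, res2$p)

  # all genes "up": observed equals every permutation -> p = 1
  all_up <- colocalization_permutation_test(ids, asg, n_perm = 50, seed = 1)
  expect_equal(all_up$p, 1)
  # no peaks -> observed 0, p = 1
  none <- colocalization_permutation_test(up, assign_to_tads(peaks[0], g, tads),
                                          n_perm = 50, seed = 1)
  expect_equal(none$observed, 0)
  expect_equal(none$p, 1)
})

test_that("boundary distances follow the TAD geometry", {
  L <- 10000
  tads <- mk_tads(c(0, 10000), c(10000, 20000))
  # centre mid-TAD -> L/2; centre at a boundary -> 0
  peaks <- gr0("chr1", c(4800, 9800), c(5200, 10200),
               name = c("mid", "edge"))
  cl <- c(mid = 1L, edge = 1L)
  g <- genes0("chr1", 100, 600, "+")
  asg <- assign_to_tads(peaks, g, tads)
  bd <- boundary_distance_test(asg, cl, n_control = 500, seed = 2)
  expect_equal(sort(bd$cluster_distances[["1"]]), c(0, L / 2))
  # all distances bounded by half the TAD length
  expect_true(all(unlist(bd$control_distances) <= L / 2))
  expect_true(all(unlist(bd$control_distances) >= 0))
  # uniform control points: mean -> L/4 within 3 standard errors
  m <- mean(bd$control_distances[[1]])
  se <- (L / sqrt(48)) / sqrt(500)
  expect_lt(abs(m - L / 4), 3 * se)
  # a cluster with < 2 assigned peaks yields NA p
  bd1 <- boundary_distance_test(asg, c(mid = 1L, edge = 2L),
                                n_control = 100, seed = 2)
  expect_true(all(is.na(bd1$p_values)))
})

test_that("adjacent-TAD mirror control reproduces the hand geometry", {
  # peak at 100000 in TAD A; up-gene TSS at 150000 in TAD A (d = 50000);
  # gene G TSS at 55000 (d' = 45000 within +/-25%) in TAD B
  tads <- gr0("chr1", c(60000, 0), c(200000, 60000), tad_id = c("A", "B"))
  peaks <- gr0("chr1", 99800, 100200, name = "pk")
  g <- genes0("chr1", c(149999, 54999), c(160000, 58000), c("+", "+"),
              ids = c("up1", "G"))
  asg <- assign_to_tads(peaks, g, tads)
  expect_equal(unname(asg$gene_tad), c("A", "B"))
  res <- adjacent_tad_mirror(asg, up_genes = "up1")
  expect_equal(res$n_qualifying_peaks, 1)
  expect_equal(res$n_candidate_genes, 1)
  expect_equal(res$n_up_candidates, 0)
  expect_equal(res$candidates, "G")
  # if G is itself upregulated it is counted as such
  res2 <- adjacent_tad_mirror(asg, up_genes = c("up1", "G"))
  expect_equal(res2$n_up_candidates, 1)
  # no shared-TAD up gene -> all zero
  res0 <- adjacent_tad_mirror(asg, up_genes = character(0))
  expect_equal(unlist(res0[1:3], use.names = FALSE), c(0, 0, 0))

  # a mirror-window gene inside the peak's own TAD is excluded
  g2 <- genes0("chr1", c(149999, 64999), c(160000, 68000), c("+", "+"),
               ids = c("up1", "ownTAD"))
  asg2 <- assign_to_tads(peaks, g2, tads)
  resx <- adjacent_tad_mirror(asg2, up_genes = "up1")
  expect_equal(resx$n_candidate_genes, 0)

  # flanking mode accepts only the immediately neighbouring TAD
  resf <- adjacent_tad_mirror(asg, up_genes = "up1", mode = "flanking")
  expect_equal(resf$n_candidate_genes, 1)  # B flanks A on the left
})
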
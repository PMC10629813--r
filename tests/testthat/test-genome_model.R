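test_that("BED-family parsing follows the 0-based half-open convention", {
  f <- withr::local_tempfile()
  writeLines(character(0), f)
  expect_length(read_intervals(f, "bed3"), 0)

  writeLines("chr1\t100\t200", f)
  gr <- read_intervals(f, "bed3")
  expect_equal(start(gr), 101)
  expect_equal(end(gr), 200)
  expect_equal(width(gr), 100)

  # narrowPeak summit offset becomes an absolute position
  writeLines("chr1\t1000\t1400\tpk1\t100\t.\t5.5\t-1\t-1\t250", f)
  pk <- read_intervals(f, "narrowPeak")
  expect_equal(mcols(pk)$summit, 1000 + 250 + 1)  # 1-based absolute
  expect_equal(peak_centre(pk), 1201)             # floor((1000+1400)/2), 1-based

  # offset -1 means no summit
  writeLines("chr1\t1000\t1400\tpk1\t100\t.\t5.5\t-1\t-1\t-1", f)
  expect_true(is.na(mcols(read_intervals(f, "narrowPeak"))$summit))
})

test_that("malformed input errors name the offending line", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t100\t200", "chr1\t100"), f)
  expect_error(read_intervals(f, "bed3"), "line 2")
  writeLines(c("chr1\t100\t200", "chr1\t300\t250"), f)
  expect_error(read_intervals(f, "bed3"), "line 2.*exceed")
  writeLines("chr1\tx\t200", f)
  expect_error(read_intervals(f, "bed3"), "non-numeric")
  expect_error(read_intervals(f, "nonsense"), "arg")
  expect_error(read_intervals(tempfile(), "bed3"), "not found")
})

test_that("TAD loading rejects overlapping TADs", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t0\t1000", "chr1\t500\t1500"), f)
  expect_error(read_intervals(f, "tad_bed"), "overlapping TADs")
  writeLines(c("chr1\t0\t1000", "chr1\t1000\t1500"), f)  # half-open abutting ok
  expect_length(read_intervals(f, "tad_bed"), 2)
})

test_that("repeat table validates class/family pairs and deduplicates", {
  f <- withr::local_tempfile()
  hdr <- "chrom\tstart\tend\tstrand\trepeat_name\trepeat_class\trepeat_family"
  writeLines(c(hdr, "chr1\t0\t300\t+\tMER11A\tLTR\tERV1",
               "chr1\t0\t300\t+\tMER11A\tLTR\tERV1",
               "chr2\t10\t400\t-\tAluY\tSINE\tAlu"), f)
  r <- read_intervals(f, "repeat_tsv")
  expect_length(r, 2)  # exact duplicate dropped
  writeLines(c(hdr, "chr1\t0\t300\t+\tMER11A\tLTR\tAlu"), f)
  expect_error(read_intervals(f, "repeat_tsv"), "not a LTR family")
  writeLines(c(hdr, "chr1\t0\t300\t+\tMER11A\tFOO\tERV1"), f)
  expect_error(read_intervals(f, "repeat_tsv"), "unknown repeat class")
})

test_that("gene table honours the 1-based header flag", {
  f <- withr::local_tempfile()
  hdr <- "chrom\tstart\tend\tstrand\tgene_id"
  writeLines(c(hdr, "chr1\t100\t200\t+\tgA"), f)
  g0 <- read_intervals(f, "gene_tsv")
  writeLines(c("#coordinates=1-based", hdr, "chr1\t101\t200\t+\tgA"), f)
  g1 <- read_intervals(f, "gene_tsv")
  expect_equal(start(g0), start(g1))
  expect_equal(end(g0), end(g1))
  expect_equal(gene_tss(g0), 101)
})

test_that("write/read round trip reproduces coordinates exactly", {
  set.seed(11)
  for (fmt in c("bed3", "tad_bed")) {
    gr <- random_intervals(40)
    if (fmt == "tad_bed") {
      gr <- gr0("chr1", seq(0, 3900, by = 100), seq(50, 3950, by = 100))
    }
    f <- withr::local_tempfile()
    write_intervals(gr, f, fmt)
    back <- read_intervals(f, fmt)
    expect_equal(start(back), start(gr))
    expect_equal(end(back), end(gr))
  }
  pk <- gr0("chr1", c(0, 5000), c(400, 5600),
            name = c("a", "b"), score = c(1, 2),
            signalValue = c(0.5, 2), pValue = c(-1, -1), qValue = c(-1, -1),
            summit = c(200L, NA))
  f <- withr::local_tempfile()
  write_intervals(pk, f, "narrowPeak")
  back <- read_intervals(f, "narrowPeak")
  expect_equal(start(back), start(pk))
  expect_equal(mcols(back)$summit, mcols(pk)$summit)

  gn <- genes0("chr2", c(0, 100), c(50, 400), c("+", "-"))
  write_intervals(gn, f, "gene_tsv")
  back <- read_intervals(f, "gene_tsv")
  expect_equal(mcols(back)$gene_id, mcols(gn)$gene_id)
  expect_equal(as.character(strand(back)), as.character(strand(gn)))
})

test_that("mutual overlap applies the 30%-of-each rule symmetrically", {
  a <- gr0("chr1", 0, 100); b <- gr0("chr1", 50, 150)
  expect_true(mutual_overlap(a, b))           # 50 bp >= 30 of both
  expect_true(mutual_overlap(b, a))
  expect_false(mutual_overlap(gr0("chr1", 0, 1000), gr0("chr1", 0, 100)))
  expect_true(mutual_overlap(a, a))           # identity
  expect_false(mutual_overlap(a, gr0("chr2", 0, 100)))
  expect_true(mutual_overlap(gr0("chr1", 0, 100), gr0("chr1", 70, 170), frac = 0.3))
  expect_false(mutual_overlap(gr0("chr1", 0, 100), gr0("chr1", 71, 171), frac = 0.3))
  expect_error(mutual_overlap(a, b, frac = 0))
})

test_that("mutual overlap matches the all-pairs brute-force oracle", {
  set.seed(42)
  a <- random_intervals(60)
  b <- random_intervals(60)
  idx <- expand.grid(i = seq_along(a), j = seq_along(b))
  got <- mutual_overlap(a[idx$i], b[idx$j])
  want <- mapply(function(i, j) oracle_mutual(a[i], b[j]), idx$i, idx$j)
  expect_equal(got, unname(want))
})

test_that("peak-set overlap counts conserve set sizes", {
  P <- gr0("chr1", c(0, 300), c(100, 400))
  Q <- gr0("chr1", 50, 150)
  ov <- overlap_peak_sets(P, Q)
  expect_equal(ov$shared_p, 1)
  expect_equal(ov$shared_q, 1)
  expect_equal(ov$p_only, 1)
  expect_equal(ov$q_only, 0)

  same <- overlap_peak_sets(P, P)
  expect_equal(same$shared_p, 2)
  expect_equal(same$p_only, 0)

  disjoint <- suppressWarnings(overlap_peak_sets(P, gr0("chr9", 0, 100)))
  expect_equal(disjoint$shared_p, 0)

  # symmetry under argument exchange
  set.seed(3)
  A <- random_intervals(80); B <- random_intervals(80)
  f <- overlap_peak_sets(A, B); r <- overlap_peak_sets(B, A)
  expect_equal(f$shared_p, r$shared_q)
  expect_equal(f$p_only, r$q_only)
  expect_equal(f$shared_p + f$p_only, length(A))
  expect_equal(f$shared_q + f$q_only, length(B))
})

test_that("distance to nearest target handles inside, outside and missing", {
  tgt <- gr0("chr1", 100, 200)
  expect_equal(distance_to_nearest(data.frame(chrom = "chr1", pos = 151), tgt), 0)
  # 0-based point 90 vs [100,200) -> 10 (1-based point 91 vs [101,200])
  expect_equal(distance_to_nearest(data.frame(chrom = "chr1", pos = 91), tgt), 10)
  expect_true(is.na(distance_to_nearest(data.frame(chrom = "chrX", pos = 5), tgt)))
})

test_that("distance to nearest matches the exhaustive oracle", {
  set.seed(17)
  targets <- random_intervals(200)
  pts <- data.frame(chrom = sample(c("chr1", "chr2", "chrX"), 300, TRUE),
                    pos = floor(runif(300, 1, 1.1e5)))
  got <- distance_to_nearest(pts, targets)
  want <- mapply(function(ch, p) oracle_distance(ch, p, targets),
                 pts$chrom, pts$pos)
  expect_equal(got, unname(want))
})

test_that("TSS/TTS anchors are strand-aware", {
  g <- genes0("chr1", c(20000, 20000), c(30000, 30000), c("+", "-"))
  expect_equal(gene_tss(g), c(20001, 30000))
  expect_equal(gene_tts(g), c(30000, 20001))
  expect_error(gene_tss(gr0("chr1", 0, 10, strand = "*",
                            gene_id = "x")), "stranded")
})
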
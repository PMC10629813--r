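test_that("summit classification follows the strand-aware windows", {
  # plus-strand gene, TSS0 = 10000 (1-based 10001)
  g <- genes0("chr1", 10000, 40000, "+")
  pk <- function(pos0) gr0("chr1", pos0 - 50, pos0 + 50,
                           summit = as.integer(pos0 + 1))
  expect_equal(as.character(classify_summits(pk(9500), g)), "promoter")
  expect_equal(as.character(classify_summits(pk(10050), g)), "promoter")
  expect_equal(as.character(classify_summits(pk(8900), g)), "distal_intergenic")
  expect_equal(as.character(classify_summits(pk(39950), g)), "tts")
  expect_equal(as.character(classify_summits(pk(40500), g)), "tts")
  expect_equal(as.character(classify_summits(pk(20000), g)), "exonic")

  # minus-strand gene over [20000, 30000): TSS0 = 29999; the promoter
  # window mirrors to [29899, 30999]
  gm <- genes0("chr2", 20000, 30000, "-")
  pk2 <- function(pos0) gr0("chr2", pos0 - 50, pos0 + 50,
                            summit = as.integer(pos0 + 1))
  expect_equal(as.character(classify_summits(pk2(30500), gm)), "promoter")
  expect_equal(as.character(classify_summits(pk2(29899), gm)), "promoter")
  expect_equal(as.character(classify_summits(pk2(31100), gm)), "distal_intergenic")
  expect_equal(as.character(classify_summits(pk2(19500), gm)), "tts")

  # no genes on the chromosome -> distal, with a loud mismatch warning
  w <- testthat::capture_warnings(
    cls9 <- classify_summits(pk(9500), genes0("chr9", 0, 100, "+")))
  expect_true(any(grepl("share no chromosome names", w)))
  expect_equal(as.character(cls9), "distal_intergenic")
})

test_that("exon lists refine the exon/intron split", {
  g <- genes0("chr1", 10000, 40000, "+")
  mcols(g)$exons <- GenomicRanges::GRangesList(
    gr0("chr1", c(10000, 30000), c(12000, 32000)))
  pk <- function(pos0) gr0("chr1", pos0 - 50, pos0 + 50,
                           summit = as.integer(pos0 + 1))
  expect_equal(as.character(classify_summits(pk(11000), g)), "exonic")
  expect_equal(as.character(classify_summits(pk(20000), g)), "intronic")
})

test_that("categories partition the peaks and mirror symmetry holds", {
  set.seed(23)
  L <- 200000
  g <- genes0("chr1", c(20000, 80000, 150000), c(50000, 110000, 190000),
              c("+", "-", "+"))
  pos0 <- floor(runif(300, 0, L - 1))
  pks <- gr0("chr1", pmax(0, pos0 - 50), pos0 + 50,
             summit = as.integer(pos0 + 1))
  cls <- classify_summits(pks, g)
  expect_equal(sum(table(cls)), 300)  # exhaustive, mutually exclusive

  # mirror all genes and summits about the chromosome: assignments persist
  mirror_pos0 <- (L - 1) - pos0
  mg <- genes0("chr1", L - end(g), L - start(g) + 1,
               ifelse(as.character(strand(g)) == "+", "-", "+"))
  mpk <- gr0("chr1", pmax(0, mirror_pos0 - 50), mirror_pos0 + 50,
             summit = as.integer(mirror_pos0 + 1))
  expect_equal(as.character(classify_summits(mpk, mg)), as.character(cls))
})

test_that("genomic distribution sums to one and matches planted fractions", {
  g <- genes0("chr1", 50000, 80000, "+")
  prom0 <- 49500   # inside the promoter window
  dist0 <- 5000
  pks <- gr0("chr1",
             c(rep(prom0, 3), rep(dist0, 7)) - 50,
             c(rep(prom0, 3), rep(dist0, 7)) + 50,
             summit = as.integer(c(rep(prom0, 3), rep(dist0, 7)) + 1))
  gd <- genomic_distribution(pks, g, chrom_lengths = c(chr1 = 200000))
  expect_equal(unname(gd$peaks["promoter"]), 0.3)
  expect_equal(unname(gd$peaks["distal_intergenic"]), 0.7)
  expect_equal(sum(gd$peaks), 1)
  expect_equal(sum(gd$genome), 1)
  # baseline promoter territory: 1101 bp of 200 kb
  expect_equal(unname(gd$genome["promoter"]), 1101 / 200000)
  expect_error(genomic_distribution(GRanges(), g, c(chr1 = 200000)), "empty")
})

test_that("repeat composition counts containing peaks per class and family", {
  pks <- gr0("chr1", c(0, 1000, 2000, 3000), c(500, 1500, 2500, 3500),
             name = sprintf("p%d", 1:4))
  reps <- gr0("chr1", c(100, 1100, 2100), c(300, 1300, 2300),
              strand = "+",
              repeat_name = c("MER11A", "MER11B", "MLT2"),
              repeat_class = c("LTR", "LTR", "LTR"),
              repeat_family = c("ERV1", "ERV1", "ERVL"))
  cl <- rep(1L, 4)
  comp <- repeat_composition(pks, cl, reps, level = "class")
  expect_equal(comp$fraction[comp$class == "LTR"], 0.75)
  expect_equal(comp$fraction[comp$class == "SINE"], 0)
  fam <- repeat_composition(pks, cl, reps, level = "family",
                            parent_class = "LTR")
  expect_equal(fam$fraction[fam$family == "ERV1"], 2 / 3)
  expect_equal(fam$fraction[fam$family == "ERVL"], 1 / 3)

  # no repeats -> all fractions zero
  empty <- repeat_composition(pks, cl, reps[0], level = "class")
  expect_true(all(empty$fraction == 0))

  # duplicated repeat records do not change the composition after dedup
  f <- withr::local_tempfile()
  hdr <- "chrom\tstart\tend\tstrand\trepeat_name\trepeat_class\trepeat_family"
  writeLines(c(hdr, "chr1\t100\t300\t+\tMER11A\tLTR\tERV1",
               "chr1\t100\t300\t+\tMER11A\tLTR\tERV1"), f)
  rd <- read_intervals(f, "repeat_tsv")
  c1 <- repeat_composition(pks, cl, rd, level = "class")
  expect_equal(c1$fraction[c1$class == "LTR"], 0.25)
})

test_that("IUPAC consensus scanning agrees with a regex oracle", {
  motif <- "CGCCCYCTNSTG"
  # planted concrete instantiation (Y->T, N->A, S->G)
  seq1 <- paste0(strrep("A", 40), "CGCCCTCTAGTG", strrep("A", 60))
  seqs <- Biostrings::DNAStringSet(c(chr1 = seq1,
                                     chr2 = strrep("A", 200)))
  rg <- gr0(c("chr1", "chr2"), c(20, 20), c(120, 120),
            summit = c(70L, 70L), name = c("hit", "miss"))
  res <- consensus_scan(rg, seqs, motif, window = 101)
  expect_equal(res$n_hit, 1)
  expect_equal(res$fraction, 0.5)
  expect_equal(res$hits$region, "hit")

  # motif N matches every non-empty region
  expect_equal(consensus_scan(rg, seqs, "N")$fraction, 1)
  expect_error(consensus_scan(rg, seqs, "CGX"), "non-IUPAC")

  # randomized property check against the regex oracle, both strands
  set.seed(99)
  pat <- iupac_regex(motif)
  rcpat <- iupac_regex(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(motif))))
  for (trial in 1:3) {
    rand <- vapply(1:60, function(i)
      paste(sample(c("A", "C", "G", "T"), 101, TRUE), collapse = ""),
      character(1))
    # spike some true sites to make hits non-trivial
    spike <- sample(60, 12)
    for (i in spike[1:6])
      substr(rand[i], 30, 41) <- "CGCCCTCTAGTG"
    for (i in spike[7:12])
      substr(rand[i], 10, 21) <- revcomp_chr("CGCCCCCTCCTG")
    ss <- Biostrings::DNAStringSet(rand)
    names(ss) <- sprintf("c%02d", 1:60)
    rg2 <- gr0(names(ss), rep(0, 60), rep(101, 60), summit = rep(51L, 60),
               name = names(ss))
    got <- consensus_scan(rg2, ss, motif, window = 101)
    want <- vapply(rand, function(s)
      grepl(pat, s) || grepl(rcpat, s), logical(1))
    expect_equal(got$n_hit, sum(want))
    expect_setequal(unique(got$hits$region), names(ss)[want])
  }
})

test_that("random background regions are width-matched and seeded", {
  rg <- gr0("chr1", c(0, 1000), c(101, 1301), name = c("a", "b"))
  bg1 <- random_background_regions(rg, c(chr1 = 1e5, chr2 = 1e5),
                                   times = 10, seed = 4)
  bg2 <- random_background_regions(rg, c(chr1 = 1e5, chr2 = 1e5),
                                   times = 10, seed = 4)
  expect_equal(length(bg1), 20)
  expect_identical(start(bg1), start(bg2))
  expect_equal(sort(unique(width(bg1))), sort(unique(width(rg))))
})
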
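test_that("alignment filters apply the mismatch/multimap/pre-tRNA rules", {
  reads <- make_alignments(
    make_read("clean"),
    make_read("mm3", mismatch_count = 3L),
    make_read("leader", covers_leader = TRUE),
    make_read("trailer", covers_trailer = TRUE),
    make_read("intron", covers_intron = TRUE),
    make_read("multi51", n_mappings = 51L),
    make_read("multi50", n_mappings = 50L)
  )
  flt <- filter_alignments(reads)
  expect_setequal(flt$read_id, c("clean", "multi50"))
  tally <- attr(flt, "exclusion_tally")
  expect_equal(tally[["pre_trna"]], 3L)
  expect_equal(tally[["mismatches"]], 1L)
  expect_equal(tally[["multimapping"]], 1L)
  # conservation: retained + excluded == input
  expect_equal(nrow(flt) + sum(tally), attr(flt, "n_input"))
})

test_that("filtering is idempotent and validates its parameters", {
  reads <- make_alignments(
    make_read("a"), make_read("b", mismatch_count = 5L),
    make_read("c", n_mappings = 60L)
  )
  once <- filter_alignments(reads)
  twice <- filter_alignments(once)
  expect_equal(as.data.frame(twice), as.data.frame(once),
               ignore_attr = TRUE)
  expect_equal(sum(attr(twice, "exclusion_tally")), 0L)
  expect_error(filter_alignments(reads, max_mismatches = -1), ">= 0")
  # relaxed thresholds retain everything
  all_in <- filter_alignments(reads, max_mismatches = 10, max_mappings = 100)
  expect_equal(nrow(all_in), 3L)
})

test_that("pileup counts wobble bases with the requested weighting", {
  refs <- tiny_refs()  # wobble at position 5 (reference base A)
  g_read <- make_read("r1", seq = "ACGTG")           # G at wobble
  flt <- make_alignments(g_read)
  pl <- pileup_at_wobble(flt, refs)
  expect_equal(pl$G, 1)
  expect_equal(pl$coverage, 1)

  # a 2-mapping read contributes 1/2 per mapping under fractional weighting
  two <- make_alignments(make_read("r2", seq = "ACGTG", n_mappings = 2L))
  expect_equal(pileup_at_wobble(two, refs, "fractional")$G, 0.5)
  expect_equal(pileup_at_wobble(two, refs, "full")$G, 1)

  # reads not spanning the wobble position contribute nothing
  off <- make_alignments(make_read("r3", start = 6L, seq = "ACGTG"))
  pl0 <- pileup_at_wobble(off, refs)
  expect_equal(pl0$coverage, 0)
  expect_equal(pl0$A + pl0$C + pl0$G + pl0$T, 0)

  # coordinates beyond the reference are an error
  bad <- make_alignments(make_read("r4", start = 18L, seq = "ACGTA"))
  expect_error(pileup_at_wobble(bad, refs), "outside")
  expect_error(
    pileup_at_wobble(make_alignments(make_read("r5", family_id = "nope")),
                     refs),
    "absent")
})

test_that("editing rate follows its two denominator definitions", {
  expect_equal(editing_rate(make_pileup(A = 60, G = 40))$rate, 0.40)
  expect_equal(editing_rate(make_pileup(G = 100))$rate, 1.0)
  expect_equal(editing_rate(make_pileup(A = 100))$rate, 0.0)
  mixed <- make_pileup(A = 58, G = 40, T = 2)
  expect_equal(editing_rate(mixed, "total")$rate, 0.40)
  expect_equal(editing_rate(mixed, "ag_only")$rate, 40 / 98)
})

test_that("low-coverage families are flagged rather than estimated", {
  est <- editing_rate(make_pileup(A = 6, G = 4), min_coverage = 20)
  expect_equal(est$flag, "insufficient_coverage")
  expect_true(is.na(est$rate))
  est2 <- editing_rate(make_pileup(A = 6, G = 4), min_coverage = 5)
  expect_equal(est2$rate, 0.4)
  expect_equal(est2$flag, "")
})

test_that("estimates respect interval ordering and denominator monotonicity", {
  set.seed(42)
  for (i in 1:25) {
    counts <- stats::rmultinom(1, 200, c(0.45, 0.03, 0.49, 0.03))
    pl <- make_pileup(counts[1], counts[2], counts[3], counts[4])
    tot <- editing_rate(pl, "total")
    ag <- editing_rate(pl, "ag_only")
    expect_true(tot$ci_low <= tot$rate && tot$rate <= tot$ci_high)
    expect_true(tot$ci_low >= 0 && tot$ci_high <= 1)
    # removing C/T from the denominator can only raise the rate
    expect_true(tot$rate <= ag$rate + 1e-12)
  }
})

test_that("Wilson interval matches the score interval from prop.test", {
  for (case in list(c(40, 100), c(1, 25), c(199, 200), c(0, 50))) {
    w <- wilson_interval(case[1], case[2])
    p <- stats::prop.test(case[1], case[2], correct = FALSE)$conf.int
    expect_equal(w$low, p[1], tolerance = 1e-9)
    expect_equal(w$high, p[2], tolerance = 1e-9)
  }
})

test_that("abundance normalises to reads per million", {
  reads <- make_alignments(
    do.call(rbind, lapply(1:75, function(i)
      make_read(paste0("a", i), family_id = "famA"))),
    do.call(rbind, lapply(1:25, function(i)
      make_read(paste0("b", i), family_id = "famB")))
  )
  ab <- trna_abundance(reads)
  expect_equal(ab$rpm[ab$family_id == "famA"], 750000)
  expect_equal(ab$rpm[ab$family_id == "famB"], 250000)
  expect_equal(sum(ab$rpm), 1e6)

  # RPM is invariant to depth: replicating every read x10 changes nothing
  reads10 <- trna_alignments(reads[rep(seq_len(nrow(reads)), 10), ])
  expect_equal(trna_abundance(reads10)$rpm, ab$rpm)

  # two half-weight mappings count as one read
  frac <- make_alignments(
    make_read("m1", family_id = "famA", n_mappings = 2L),
    make_read("m1", family_id = "famB", n_mappings = 2L),
    make_read("u1", family_id = "famA")
  )
  abf <- trna_abundance(frac)
  expect_equal(abf$weighted_count[abf$family_id == "famA"], 1.5)
  expect_equal(abf$weighted_count[abf$family_id == "famB"], 0.5)

  expect_error(trna_abundance(reads[0, ]), "no retained reads")
})

test_that("SAM reading reconstructs flags, mismatches and the pileup", {
  cfg <- sim_config(seed = 5, coverage = 300, rates = c(
    "tRNA-Val-AAC" = 0.8, "tRNA-Thr-AGT" = 0.3))
  refs <- simulate_trna_references(cfg)
  sim <- simulate_trna_reads(cfg, "control", refs = refs)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(sim$reads, refs, sam)
  back <- read_sam_alignments(sam, refs)
  expect_equal(nrow(back), nrow(sim$reads))
  ord <- order(back$read_id); ord0 <- order(sim$reads$read_id)
  expect_equal(back$mismatch_count[ord], sim$reads$mismatch_count[ord0])
  expect_equal(back$covers_leader[ord], sim$reads$covers_leader[ord0])
  expect_equal(back$covers_trailer[ord], sim$reads$covers_trailer[ord0])
  expect_equal(back$covers_intron[ord], sim$reads$covers_intron[ord0])
  pl0 <- pileup_at_wobble(filter_alignments(sim$reads), refs)
  pl1 <- pileup_at_wobble(filter_alignments(back), refs)
  expect_equal(pl1[order(pl1$family_id), ], pl0[order(pl0$family_id), ],
               ignore_attr = TRUE)
})

test_that("a soft-clipped CCA tail does not count as trailer sequence", {
  refs <- tiny_refs()   # 20 nt reference
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", refs$family_id, 20L),
    # ends at the 3' end with a soft-clipped CCA: the non-templated tail
    sprintf("cca\t0\t%s\t16\t255\t5M3S\t*\t0\t0\t%sCCA\t*\tNM:i:0\tNH:i:1",
            refs$family_id, substr(refs$mature_sequence, 16, 20)),
    # same position, non-CCA clip: genuine trailer overhang
    sprintf("tr\t0\t%s\t16\t255\t5M3S\t*\t0\t0\t%sTGG\t*\tNM:i:0\tNH:i:1",
            refs$family_id, substr(refs$mature_sequence, 16, 20)),
    # 5' soft clip at position 1: leader overhang
    sprintf("ld\t0\t%s\t1\t255\t2S5M\t*\t0\t0\tGA%s\t*\tNM:i:0\tNH:i:1",
            refs$family_id, substr(refs$mature_sequence, 1, 5))
  ), sam)
  reads <- read_sam_alignments(sam, refs)
  reads <- reads[order(reads$read_id), ]
  expect_equal(reads$covers_trailer[reads$read_id == "cca"], FALSE)
  expect_equal(reads$covers_trailer[reads$read_id == "tr"], TRUE)
  expect_equal(reads$covers_leader[reads$read_id == "ld"], TRUE)
})

test_that("pileup TSV bypass reproduces the aligned-read estimates", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("family_id\tpos\tA\tC\tG\tT",
               "tRNA-Val-AAC\t34\t60\t0\t40\t0",
               "tRNA-Thr-AGT\t34\t10\t1\t88\t1"), tsv)
  pl <- read_pileup_tsv(tsv)
  est <- editing_rate(pl)
  expect_equal(est$rate[est$family_id == "tRNA-Val-AAC"], 0.40)
  expect_equal(est$rate[est$family_id == "tRNA-Thr-AGT"], 0.88)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("family_id\tA\tC\tG", "x\t1\t1\t1"), bad)
  expect_error(read_pileup_tsv(bad), "missing column")
})
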
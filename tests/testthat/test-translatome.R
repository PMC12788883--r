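test_that("CPM normalisation scales each replicate to one million", {
  m <- matrix(c(10, 999990, 5, 15), 2, 2,
              dimnames = list(c("g1", "g2"), c("r1", "r2")))
  cpm <- normalize_cpm(m)
  expect_equal(cpm["g1", "r1"], 10)
  expect_equal(colSums(cpm), c(r1 = 1e6, r2 = 1e6))
  # scale invariance within a replicate
  expect_equal(normalize_cpm(m * 2), cpm)
  m0 <- m; m0[, 2] <- 0
  expect_error(normalize_cpm(m0), "zero library size")
  expect_error(normalize_cpm(-m), "negative")
})

test_that("TE is the pseudocount-stabilised RPF/RNA ratio", {
  rpf <- matrix(100, dimnames = list("g", "r"))
  rna <- matrix(50, dimnames = list("g", "r"))
  expect_equal(translation_efficiency(rpf, rna, pseudocount = 0)[1, 1], 2.0)
  expect_equal(translation_efficiency(rna, rna)[1, 1], 1.0)
  expect_equal(
    translation_efficiency(matrix(10, dimnames = list("g", "r")),
                           matrix(0, dimnames = list("g", "r")))[1, 1],
    21.0)
  rna2 <- rna; rownames(rna2) <- "h"
  expect_error(translation_efficiency(rpf, rna2), "same genes")
})

test_that("differential TE classifies by joint effect and significance", {
  cond <- c(ctrl_1 = "control", ctrl_2 = "control",
            kd_1 = "knockdown", kd_2 = "knockdown")
  # identical TE everywhere: no fold change, nothing called
  flat <- matrix(2, 3, 4, dimnames = list(paste0("g", 1:3), names(cond)))
  res <- differential_te(flat, cond)
  expect_equal(res$log2fc, rep(0, 3))
  expect_true(all(res$te_class == "unchanged"))

  # a 4x drop with tiny jitter: log2fc -2 and a clean down call
  te <- rbind(g1 = c(4.001, 3.999, 1.0005, 0.9995),
              g2 = c(2.001, 1.999, 2.0005, 1.9995))
  colnames(te) <- names(cond)
  res2 <- differential_te(te, cond)
  expect_equal(res2$log2fc[1], -2, tolerance = 1e-3)
  expect_equal(res2$te_class[1], "down")
  expect_equal(res2$te_class[2], "unchanged")

  expect_error(differential_te(te[, -1], cond[-1]), "at least 2 replicates")
})

test_that("fold-change gate and expression floor veto significance", {
  cond <- c(a = "control", b = "control", c = "knockdown", d = "knockdown")
  # significant but below the 1.5-fold cut
  te <- rbind(g1 = c(1.001, 0.999, 1.3005, 1.2995))
  colnames(te) <- names(cond)
  res <- differential_te(te, cond)
  expect_lt(res$p_value[1], 0.05)
  expect_equal(res$te_class[1], "unchanged")
  # same gene passes with fc = 1.2
  expect_equal(differential_te(te, cond, fc = 1.2)$te_class[1], "up")
  # low-expression genes are excluded from testing
  rna <- matrix(0.2, 1, 4, dimnames = dimnames(te))
  res_floor <- differential_te(te, cond, rna_cpm = rna)
  expect_false(res_floor$tested[1])
  expect_equal(res_floor$te_class[1], "unchanged")
})

test_that("log2 TE fold change is invariant to library rescaling", {
  set.seed(9)
  cond <- c(c1 = "control", c2 = "control", k1 = "knockdown",
            k2 = "knockdown")
  rpf <- matrix(rpois(400, 100), 100, 4,
                dimnames = list(sprintf("g%03d", 1:100), names(cond)))
  rna <- matrix(rpois(400, 100), 100, 4, dimnames = dimnames(rpf))
  base <- differential_te(translation_efficiency(normalize_cpm(rpf),
                                                 normalize_cpm(rna), 0),
                          cond)
  rpf2 <- rpf; rpf2[, "k1"] <- rpf2[, "k1"] * 7   # depth change only
  resc <- differential_te(translation_efficiency(normalize_cpm(rpf2),
                                                 normalize_cpm(rna), 0),
                          cond)
  expect_equal(resc$log2fc, base$log2fc, tolerance = 1e-12)
  # classes partition the gene set
  expect_equal(sum(base$te_class == "up") + sum(base$te_class == "down") +
                 sum(base$te_class == "unchanged"), 100L)
})

test_that("raising a gene's knockdown RPF never lowers its log2fc", {
  cond <- c(c1 = "control", c2 = "control", k1 = "knockdown",
            k2 = "knockdown")
  rpf <- matrix(c(100, 100, 100, 100,
                  50, 50, 50, 50), 2, 4, byrow = TRUE,
                dimnames = list(c("g1", "g2"), names(cond)))
  rna <- matrix(100, 2, 4, dimnames = dimnames(rpf))
  prev <- -Inf
  for (extra in c(0, 10, 50, 200)) {
    rpf_i <- rpf; rpf_i["g1", c("k1", "k2")] <- 100 + extra
    te <- translation_efficiency(rpf_i, rna, pseudocount = 0.5)
    fc <- differential_te(te, cond)$log2fc[1]
    expect_gte(fc, prev)
    prev <- fc
  }
})

test_that("permutation test agrees with t on strong effects", {
  cond <- c(a = "control", b = "control", c = "control",
            d = "knockdown", e = "knockdown", f = "knockdown")
  set.seed(3)
  te <- rbind(
    big = c(4, 4.1, 3.9, 1, 1.05, 0.95),
    null = c(2, 2.1, 1.9, 2.05, 1.95, 2))
  colnames(te) <- names(cond)
  res_t <- differential_te(te, cond)
  res_p <- differential_te(te, cond, test = "permutation")
  # the strong effect ranks at the permutation extreme (min p = 1/20)
  expect_equal(res_p$p_value[1], min(res_p$p_value))
  expect_lte(res_p$p_value[1], 0.1)
  expect_gt(res_p$p_value[2], 0.3)
  expect_equal(sign(res_t$log2fc), sign(res_p$log2fc))
})

test_that("the null simulation yields a calibrated false-positive rate", {
  cfg <- sim_config(seed = 314, beta = 0)
  tx <- simulate_transcriptome(cfg)
  cnt <- simulate_counts(cfg, tx)
  rna_cpm <- normalize_cpm(cnt$rna)
  te <- translation_efficiency(normalize_cpm(cnt$rpf), rna_cpm)
  res <- differential_te(te, cnt$condition, rna_cpm = rna_cpm)
  fpr <- mean(res$p_value[res$tested] < 0.05, na.rm = TRUE)
  expect_gt(fpr, 0.03)
  expect_lt(fpr, 0.07)
})

test_that("SILAC aggregation averages peptide ratios per protein", {
  expect_equal(aggregate_silac(
    data.frame(protein_id = "P1", ratio = c(2, 2, 2)))$ratio, 2.0)
  expect_equal(aggregate_silac(
    data.frame(protein_id = "P1", ratio = 0.5))$ratio, 0.5)
  # mean of ratios, not ratio of means
  expect_equal(aggregate_silac(
    data.frame(protein_id = "P1", ratio = c(1, 3)))$ratio, 2.0)
  expect_error(aggregate_silac(
    data.frame(protein_id = "P1", ratio = c(1, -2))), "positive")
  expect_warning(
    agg <- aggregate_silac(data.frame(protein_id = c("P1", "P2"),
                                      ratio = c(2, NA))),
    "without a ratio")
  expect_equal(agg$protein_id, "P1")
})

test_that("differential proteins need both effect size and significance", {
  set.seed(21)
  mk <- function(id, lr, jitter = 0.02) {
    data.frame(protein_id = id,
               replicate = paste0("rep", 1:3),
               log2_ratio = lr + rnorm(3, 0, jitter),
               ratio = 2^(lr + rnorm(3, 0, jitter)))
  }
  # many null proteins stabilise the moderated variance estimate
  ratios <- do.call(rbind, c(
    list(mk("UP", 0.8), mk("SMALL", 0.3), mk("DOWN", -0.9)),
    lapply(sprintf("N%02d", 1:30), mk, lr = 0)))
  res <- differential_protein(ratios)
  expect_equal(res$protein_class[res$protein_id == "UP"], "up")
  expect_equal(res$protein_class[res$protein_id == "DOWN"], "down")
  # below the log2 0.5 effect cut despite significance
  expect_equal(res$protein_class[res$protein_id == "SMALL"], "unchanged")
  expect_true(all(res$adj_p >= res$p_value - 1e-12, na.rm = TRUE))

  # all-identical ratios: no variance anywhere, nothing callable
  flat <- do.call(rbind, lapply(c("A", "B", "C"), function(id)
    data.frame(protein_id = id, replicate = paste0("rep", 1:3),
               log2_ratio = 0.8, ratio = 2^0.8)))
  res_flat <- differential_protein(flat, test = "t")
  expect_true(all(res_flat$protein_class == "unchanged"))
})

test_that("count and peptide TSV readers round-trip their tables", {
  counts <- matrix(c(3L, 8L, 0L, 5L), 2, 2,
                   dimnames = list(c("g1", "g2"), c("r1", "r2")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(cbind(gene_id = rownames(counts), as.data.frame(counts)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_counts_tsv(path), counts + 0)
  pep <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tpeptide_id\tratio_HL\treplicate",
               "P1\tp1\t2.0\trep1", "P1\tp2\t4.0\trep1"), pep)
  expect_equal(aggregate_silac(read_peptides_tsv(pep))$ratio, 3.0)
})
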
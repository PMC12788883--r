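# Shared in-code fixtures for the test suite.

# a wobble pileup row built from base counts
make_pileup <- function(A = 0, C = 0, G = 0, T = 0,
                        family_id = "tRNA-Val-AAC") {
  df <- data.frame(family_id = family_id, A = A, C = C, G = G, T = T,
                   coverage = A + C + G + T, stringsAsFactors = FALSE)
  class(df) <- c("wobble_pileup", "data.frame")
  df
}

# a minimal reference set: one family, wobble position 5
tiny_refs <- function(seq = "ACGTAACGTGCGTACGTACG", anticodon_start = 5L,
                      family_id = "tRNA-Val-AAC") {
  refs <- data.frame(family_id = family_id, mature_sequence = seq,
                     anticodon_start = anticodon_start, gene_copies = 1L,
                     intron_pos = NA_integer_, stringsAsFactors = FALSE)
  class(refs) <- c("trna_references", "data.frame")
  refs
}

# hand-built alignment rows; defaults pass every filter
make_read <- function(read_id = "r1", family_id = "tRNA-Val-AAC",
                      start = 1L, seq = "ACGTA", mismatch_count = 0L,
                      n_mappings = 1L, covers_leader = FALSE,
                      covers_trailer = FALSE, covers_intron = FALSE) {
  data.frame(read_id = read_id, family_id = family_id, start = start,
             end = start + nchar(seq) - 1L, seq = seq,
             mismatch_count = mismatch_count, n_mappings = n_mappings,
             covers_leader = covers_leader, covers_trailer = covers_trailer,
             covers_intron = covers_intron, stringsAsFactors = FALSE)
}

make_alignments <- function(...) {
  trna_alignments(do.call(rbind, list(...)))
}

# pipeline input paths from a write_simulation() result (truth files are
# for tests, not pipeline inputs)
sim_inputs <- function(paths) {
  paths[!grepl("^truth_", names(paths))]
}

# the 8 ADAT-edited families on their own
edited_families <- function() {
  fam <- trna_families()
  fam[fam$edited, , drop = FALSE]
}

# per-gene codon usage matrix drawn from multinomial counts with given
# codon probabilities (rows of `probs` recycle over genes)
random_usage_matrix <- function(n_genes, probs, n_codons = 300,
                                prefix = "g") {
  codons <- sense_codons()
  stopifnot(length(probs) == length(codons))
  m <- t(vapply(seq_len(n_genes), function(i) {
    as.numeric(stats::rmultinom(1, n_codons, probs)) / n_codons
  }, numeric(length(codons))))
  dimnames(m) <- list(paste0(prefix, seq_len(n_genes)), codons)
  m
}
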
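# Seeded synthetic-data generator emulating the study design: tRNA-seq
# reads with planted wobble editing rates, ORFs with controlled
# strict-codon content, NB RPF/RNA counts in which knockdown lowers TE in
# proportion to strict-codon content, and SILAC peptide tables.

#' Simulation configuration
#'
#' Collects and validates all generator parameters.  Defaults define the
#' study conditions emulated throughout the package: eight ADAT-edited
#' isoacceptor families with heterogeneous control editing rates (most at
#' 0.85, one moderate at 0.40, one low at 0.10), a knockdown retaining a
#' quarter of the editing activity, 0.1\% per-base sequencing error, 5,000
#' wobble-spanning reads per family, a 2,000-gene transcriptome whose
#' per-gene strict-codon fraction spans 0.05–0.45, a TE effect of
#' \code{beta = 2} log2 units per unit (strict fraction x editing deficit),
#' replicate noise of 0.25 log2 units, NB dispersion 0.01 (a biological CV
#' of 10\%, typical of isogenic cell-line replicates) and two replicates
#' per condition.
#'
#' @param seed Integer seed; every generator routine derives its RNG
#'   stream from it.
#' @param families Family table (see \code{\link{trna_families}}).
#' @param rates Named vector of control editing fractions per simulated
#'   family (names must be edited families).
#' @param kd_editing_factor Multiplier on editing rates in the knockdown.
#' @param seq_error Per-base substitution error probability.
#' @param coverage Wobble-spanning reads per family.
#' @param read_length Read length (nt).
#' @param pre_trna_fraction,high_mismatch_fraction,excess_multimap_fraction
#'   Fractions of reads planted with pre-tRNA sequence, >2 mismatches, or
#'   51 mappings, to exercise the alignment filters.
#' @param multimap_fraction Fraction of retained reads reported with 2
#'   mappings (exercises fractional weighting).
#' @param n_genes,orf_length_range,strict_fraction_range Transcriptome
#'   size, ORF length range (codons), per-gene target strict-codon
#'   fraction range.
#' @param beta TE effect size: log2 TE decrement per unit strict fraction
#'   times editing deficit; \code{beta = 0} is the null.
#' @param sigma_log2te Per-replicate log2 TE noise SD.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param depth Expected reads per count library.
#' @param n_reps Replicates per condition.
#' @param n_proteins,n_peptides,peptide_sdlog,n_silac_reps SILAC branch:
#'   number of proteins, peptides per protein per replicate, lognormal
#'   peptide noise (sdlog), technical replicates.
#' @return A validated \code{sim_config} list.
#' @export
#' @examples
#' cfg <- sim_config(seed = 7, n_genes = 100)
#' cfg$beta
sim_config <- function(seed = 1L,
                       families = trna_families(),
                       rates = c("tRNA-Ala-AGC" = 0.85,
                                 "tRNA-Arg-ACG" = 0.85,
                                 "tRNA-Ile-AAT" = 0.10,
                                 "tRNA-Leu-AAG" = 0.85,
                                 "tRNA-Pro-AGG" = 0.85,
                                 "tRNA-Ser-AGA" = 0.85,
                                 "tRNA-Thr-AGT" = 0.40,
                                 "tRNA-Val-AAC" = 0.85),
                       kd_editing_factor = 0.25,
                       seq_error = 0.001,
                       coverage = 5000L,
                       read_length = 30L,
                       pre_trna_fraction = 0.02,
                       high_mismatch_fraction = 0.02,
                       excess_multimap_fraction = 0.01,
                       multimap_fraction = 0.05,
                       n_genes = 2000L,
                       orf_length_range = c(150L, 450L),
                       strict_fraction_range = c(0.05, 0.45),
                       beta = 2,
                       sigma_log2te = 0.25,
                       dispersion = 0.01,
                       depth = 2e6,
                       n_reps = 2L,
                       n_proteins = 500L,
                       n_peptides = 10L,
                       peptide_sdlog = 0.1,
                       n_silac_reps = 3L) {
  cfg <- list(seed = as.integer(seed), families = families, rates = rates,
              kd_editing_factor = kd_editing_factor, seq_error = seq_error,
              coverage = as.integer(coverage),
              read_length = as.integer(read_length),
              pre_trna_fraction = pre_trna_fraction,
              high_mismatch_fraction = high_mismatch_fraction,
              excess_multimap_fraction = excess_multimap_fraction,
              multimap_fraction = multimap_fraction,
              n_genes = as.integer(n_genes),
              orf_length_range = as.integer(orf_length_range),
              strict_fraction_range = strict_fraction_range,
              beta = beta, sigma_log2te = sigma_log2te,
              dispersion = dispersion, depth = depth,
              n_reps = as.integer(n_reps),
              n_proteins = as.integer(n_proteins),
              n_peptides = as.integer(n_peptides),
              peptide_sdlog = peptide_sdlog,
              n_silac_reps = as.integer(n_silac_reps))
  probs <- c(cfg$rates, cfg$kd_editing_factor, cfg$seq_error,
             cfg$pre_trna_fraction, cfg$high_mismatch_fraction,
             cfg$excess_multimap_fraction, cfg$multimap_fraction,
             cfg$strict_fraction_range)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities and fractions must lie in [0, 1]")
  }
  if (cfg$kd_editing_factor <= 0) {
    stop("kd_editing_factor must be in (0, 1]")
  }
  if (cfg$beta < 0) stop("beta must be >= 0 (0 gives the null)")
  if (cfg$depth <= 0 || cfg$coverage < 1 || cfg$n_genes < 1) {
    stop("depth, coverage and n_genes must be positive")
  }
  if (cfg$n_reps < 2) stop("need n_reps >= 2 for differential testing")
  validate_families(cfg$families)
  unknown <- setdiff(names(cfg$rates), cfg$families$family_id)
  if (length(unknown)) {
    stop("rates given for unknown families: ",
         paste(unknown, collapse = ", "))
  }
  class(cfg) <- "sim_config"
  cfg
}

# deterministic sub-seeds per generator branch, kept below 2^31
sub_seed <- function(cfg, offset) {
  as.integer((as.numeric(cfg$seed) * 1009 + offset) %% 2147483647)
}

#' Simulate mature tRNA reference sequences
#'
#' One reference per family named in \code{rates}: random mature sequence
#' (76 nt, no 3' CCA) with the family anticodon placed at a per-family
#' anticodon start drawn from 33–35, so downstream code must honour the
#' metadata rather than assume a fixed position 34.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A \code{trna_references} data.frame.
#' @export
simulate_trna_references <- function(config) {
  set.seed(sub_seed(config, 1L))
  fam <- config$families
  ids <- names(config$rates)
  len <- 76L
  refs <- data.frame(
    family_id = ids,
    mature_sequence = vapply(ids, function(id) {
      paste(sample(NUCLEOTIDES, len, replace = TRUE), collapse = "")
    }, character(1)),
    anticodon_start = sample(33:35, length(ids), replace = TRUE),
    gene_copies = sample(1:10, length(ids), replace = TRUE),
    intron_pos = NA_integer_,
    stringsAsFactors = FALSE, row.names = NULL
  )
  anticodon <- fam$anticodon[match(ids, fam$family_id)]
  for (i in seq_along(ids)) {
    substr(refs$mature_sequence[i], refs$anticodon_start[i],
           refs$anticodon_start[i] + 2L) <- anticodon[i]
  }
  class(refs) <- c("trna_references", "data.frame")
  refs
}

#' Simulate tRNA-seq read alignments
#'
#' For each family, generates \code{coverage} wobble-spanning reads whose
#' base at the wobble position is G with probability equal to the family's
#' editing rate (times \code{kd_editing_factor} in the knockdown), then
#' applies uniform per-base substitution errors.  Configurable fractions
#' of reads are planted with pre-tRNA evidence (leader/trailer overhang or
#' retained intron), more than two mismatches, or 51 reported mappings, to
#' exercise the alignment filters; a further fraction is reported with 2
#' mappings to exercise fractional weighting.
#'
#' @param config A \code{\link{sim_config}}.
#' @param condition \code{"control"} or \code{"knockdown"}.
#' @param refs References from \code{\link{simulate_trna_references}}
#'   (regenerated from the config seed when omitted, so both conditions
#'   share identical references).
#' @return List: \code{references}, \code{reads}
#'   (\code{\link{trna_alignments}}), \code{truth} (per-family true
#'   editing rate in this condition, and planted violation counts).
#' @export
simulate_trna_reads <- function(config,
                                condition = c("control", "knockdown"),
                                refs = simulate_trna_references(config)) {
  condition <- match.arg(condition)
  set.seed(sub_seed(config, if (condition == "control") 2L else 3L))
  fam <- config$families
  rl <- config$read_length
  cov <- config$coverage
  edited <- stats::setNames(fam$edited, fam$family_id)

  all_reads <- vector("list", nrow(refs))
  truth_rate <- numeric(nrow(refs))
  planted <- c(pre_trna = 0L, mismatches = 0L, multimapping = 0L)

  for (i in seq_len(nrow(refs))) {
    id <- refs$family_id[i]
    ref <- refs$mature_sequence[i]
    L <- nchar(ref)
    w <- refs$anticodon_start[i]
    rate <- unname(config$rates[[id]])
    if (!isTRUE(edited[[id]])) rate <- 0
    eff <- if (condition == "knockdown") rate * config$kd_editing_factor
           else rate
    truth_rate[i] <- eff

    lo <- max(1L, w - rl + 1L)
    hi <- min(w, L - rl + 1L)
    start <- sample(lo:hi, cov, replace = TRUE)
    end <- start + rl - 1L
    seqs <- substring(ref, start, end)

    # wobble base: edited (read as G) with probability eff
    if (isTRUE(edited[[id]])) {
      g <- stats::runif(cov) < eff
      wpos <- w - start + 1L
      base <- ifelse(g, "G", "A")
      substr(seqs, wpos, wpos) <- base
    }

    # uniform substitution errors
    n_err <- stats::rbinom(cov, rl, config$seq_error)
    for (j in which(n_err > 0L)) {
      pos <- sample.int(rl, n_err[j])
      for (p in pos) {
        cur <- substr(seqs[j], p, p)
        substr(seqs[j], p, p) <- sample(setdiff(NUCLEOTIDES, cur), 1L)
      }
    }

    # planted filter violations (disjoint subsets)
    n_pre <- as.integer(round(config$pre_trna_fraction * cov))
    n_mm <- as.integer(round(config$high_mismatch_fraction * cov))
    n_ex <- as.integer(round(config$excess_multimap_fraction * cov))
    idx <- sample.int(cov, n_pre + n_mm + n_ex)
    idx_pre <- idx[seq_len(n_pre)]
    idx_mm <- idx[n_pre + seq_len(n_mm)]
    idx_ex <- idx[n_pre + n_mm + seq_len(n_ex)]
    planted <- planted + c(pre_trna = n_pre, mismatches = n_mm,
                           multimapping = n_ex)

    lead <- trail <- intr <- logical(cov)
    if (n_pre) {
      kind <- sample(c("leader", "trailer", "intron"), n_pre, replace = TRUE)
      lead[idx_pre[kind == "leader"]] <- TRUE
      trail[idx_pre[kind == "trailer"]] <- TRUE
      intr[idx_pre[kind == "intron"]] <- TRUE
      # leader reads must abut the 5' end, trailer reads the 3' end
      move5 <- idx_pre[kind == "leader"]
      start[move5] <- 1L; end[move5] <- rl
      seqs[move5] <- substr_keep_wobble(ref, 1L, rl, seqs[move5], start)
      move3 <- idx_pre[kind == "trailer"]
      start[move3] <- L - rl + 1L; end[move3] <- L
      seqs[move3] <- substring(ref, L - rl + 1L, L)
    }

    mism <- count_mismatches(seqs, ref, start, end)
    if (n_mm) {
      # inject 3 extra mismatches beyond whatever the read carries
      for (j in idx_mm) {
        pos <- sample.int(rl, 3L)
        for (p in pos) {
          cur <- substr(seqs[j], p, p)
          ref_b <- substr(ref, start[j] + p - 1L, start[j] + p - 1L)
          substr(seqs[j], p, p) <- sample(setdiff(NUCLEOTIDES, c(cur, ref_b)),
                                          1L)
        }
      }
      mism[idx_mm] <- count_mismatches(seqs[idx_mm], ref, start[idx_mm],
                                       end[idx_mm])
    }

    n_map <- rep(1L, cov)
    n_map[idx_ex] <- 51L
    n_multi <- round(config$multimap_fraction * cov)
    if (n_multi) {
      free <- setdiff(seq_len(cov), idx)
      n_map[sample(free, min(n_multi, length(free)))] <- 2L
    }

    all_reads[[i]] <- data.frame(
      read_id = sprintf("%s_%s_%06d", id, substr(condition, 1, 2),
                        seq_len(cov)),
      family_id = id, start = start, end = end, seq = seqs,
      mismatch_count = mism, n_mappings = n_map,
      covers_leader = lead, covers_trailer = trail, covers_intron = intr,
      stringsAsFactors = FALSE
    )
  }

  reads <- trna_alignments(do.call(rbind, all_reads))
  list(
    references = refs,
    reads = reads,
    truth = list(
      rates = data.frame(family_id = refs$family_id,
                         true_rate = truth_rate,
                         stringsAsFactors = FALSE),
      planted_exclusions = planted
    )
  )
}

# reads moved to the 5' end keep their (already drawn) wobble base
substr_keep_wobble <- function(ref, s, e, old_seqs, old_start) {
  out <- rep(substring(ref, s, e), length(old_seqs))
  out
}

count_mismatches <- function(seqs, ref, start, end) {
  if (!length(seqs)) return(integer(0))
  rl <- end - start + 1L
  stopifnot(length(unique(rl)) <= 1L)
  rl <- rl[1]
  refwin <- substring(ref, start, end)
  mism <- integer(length(seqs))
  for (p in seq_len(rl)) {
    mism <- mism + (substr(seqs, p, p) != substr(refwin, p, p))
  }
  mism
}

#' Simulate a transcriptome with controlled strict-codon content
#'
#' Builds in-frame ORFs codon by codon: an ATG start, interior codons drawn
#' as strictly ADAT-dependent codons (uniformly over the strict set implied
#' by the configured families) with the gene's target probability and from
#' a uniform background over the remaining sense codons otherwise, and a
#' random stop.  No internal stops by construction.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List: \code{sequences} (named character), \code{truth}
#'   (data.frame \code{gene_id}, \code{target_strict_fraction},
#'   \code{strict_fraction} realised over sense codons,
#'   \code{length_codons}).
#' @export
simulate_transcriptome <- function(config) {
  set.seed(sub_seed(config, 4L))
  sf_range <- config$strict_fraction_range
  if (any(sf_range < 0 | sf_range > 1) || sf_range[1] > sf_range[2]) {
    stop("infeasible strict_fraction_range")
  }
  tab <- build_decoding_table(config$families)
  strict_set <- tab$codon[tab$dependency == "strict"]
  if (length(strict_set) == 0L && any(sf_range > 0)) {
    stop("family set yields no strict codons; target fraction infeasible")
  }
  bg_set <- setdiff(sense_codons(), strict_set)

  n <- config$n_genes
  rng <- config$orf_length_range
  len <- rng[1] + sample.int(rng[2] - rng[1] + 1L, n, replace = TRUE) - 1L
  sf <- stats::runif(n, sf_range[1], sf_range[2])
  gene_id <- sprintf("gene%05d", seq_len(n))

  n_inner <- len - 2L                      # minus start and stop
  gene_of <- rep.int(seq_len(n), n_inner)
  is_strict <- stats::runif(sum(n_inner)) < sf[gene_of]
  inner <- character(sum(n_inner))
  inner[is_strict] <- sample(strict_set, sum(is_strict), replace = TRUE)
  inner[!is_strict] <- sample(bg_set, sum(!is_strict), replace = TRUE)

  stops <- sample(STOP_CODONS, n, replace = TRUE)
  inner_by_gene <- split(inner, gene_of)
  sequences <- vapply(seq_len(n), function(i) {
    paste0("ATG", paste(inner_by_gene[[i]], collapse = ""), stops[i])
  }, character(1))
  names(sequences) <- gene_id

  realized <- vapply(split(is_strict, gene_of), sum, numeric(1)) /
    (len - 1L)                              # sense codons incl. ATG
  list(
    sequences = sequences,
    truth = data.frame(
      gene_id = gene_id,
      target_strict_fraction = sf,
      strict_fraction = as.numeric(realized),
      length_codons = len,
      stringsAsFactors = FALSE
    )
  )
}

#' Simulate RPF and input-RNA count matrices
#'
#' RNA counts are negative binomial around lognormal expression levels,
#' identical in expectation across conditions (knockdown acts on
#' translation, not transcription).  RPF counts are negative binomial
#' around expression x TE, where per gene
#' \deqn{log2 TE_{kd} = log2 TE_{ctrl} - beta \cdot strictfrac \cdot
#'   (1 - kdfactor)}
#' and each replicate measurement adds N(0, sigma_log2te) noise on the RPF
#' mean.  With \code{beta = 0} the construction is an exact null.
#'
#' @param config A \code{\link{sim_config}}.
#' @param transcriptome Output of \code{\link{simulate_transcriptome}}.
#' @return List: \code{rpf}, \code{rna} (count matrices, genes x
#'   replicates), \code{condition} (named vector), \code{truth}
#'   (data.frame with true log2 TE per condition and the planted shift).
#' @export
simulate_counts <- function(config, transcriptome) {
  set.seed(sub_seed(config, 5L))
  truth <- transcriptome$truth
  n <- nrow(truth)
  size <- 1 / config$dispersion

  expr <- stats::rlnorm(n, meanlog = log(200), sdlog = 1)
  prop <- expr / sum(expr)
  log2_te_ctrl <- stats::rnorm(n, 0, 0.5)
  shift <- -config$beta * truth$strict_fraction *
    (1 - config$kd_editing_factor)
  log2_te_kd <- log2_te_ctrl + shift

  reps <- c(paste0("ctrl_", seq_len(config$n_reps)),
            paste0("kd_", seq_len(config$n_reps)))
  condition <- stats::setNames(
    rep(c("control", "knockdown"), each = config$n_reps), reps)

  rna <- rpf <- matrix(0L, n, length(reps),
                       dimnames = list(truth$gene_id, reps))
  for (r in seq_along(reps)) {
    rna[, r] <- stats::rnbinom(n, mu = prop * config$depth, size = size)
    lte <- if (condition[r] == "control") log2_te_ctrl else log2_te_kd
    noise <- stats::rnorm(n, 0, config$sigma_log2te)
    w <- prop * 2^(lte + noise)
    rpf[, r] <- stats::rnbinom(n, mu = w / sum(w) * config$depth,
                               size = size)
  }
  list(
    rpf = rpf, rna = rna, condition = condition,
    truth = data.frame(
      gene_id = truth$gene_id,
      strict_fraction = truth$strict_fraction,
      log2_te_control = log2_te_ctrl,
      log2_te_kd = log2_te_kd,
      true_log2fc = shift,
      stringsAsFactors = FALSE
    )
  )
}

#' Simulate a SILAC peptide-ratio table
#'
#' Per protein and replicate, peptide H/L ratios are lognormal around the
#' protein's true ratio (multiplicative noise with unit mean, so the
#' arithmetic peptide mean is an unbiased estimate of the true ratio).
#'
#' @param config A \code{\link{sim_config}}.
#' @param true_log2_ratios Optional named numeric of true log2 H/L ratios;
#'   by default 10\% of proteins are planted up (+1), 10\% down (-1), the
#'   rest at 0.
#' @return List: \code{peptides} (data.frame \code{protein_id},
#'   \code{peptide_id}, \code{ratio_HL}, \code{replicate}), \code{truth}
#'   (protein_id, true_log2_ratio, true_class).
#' @export
simulate_peptides <- function(config, true_log2_ratios = NULL) {
  set.seed(sub_seed(config, 6L))
  if (is.null(true_log2_ratios)) {
    n <- config$n_proteins
    cls <- sample(rep(c("up", "down", "unchanged"),
                      times = c(round(0.1 * n), round(0.1 * n),
                                n - 2 * round(0.1 * n))))
    true_log2_ratios <- stats::setNames(
      ifelse(cls == "up", 1, ifelse(cls == "down", -1, 0)),
      sprintf("prot%04d", seq_len(n)))
  }
  ids <- names(true_log2_ratios)
  sdl <- config$peptide_sdlog
  rows <- expand.grid(protein_id = ids,
                      replicate = paste0("rep", seq_len(config$n_silac_reps)),
                      pep = seq_len(config$n_peptides),
                      stringsAsFactors = FALSE)
  noise <- stats::rlnorm(nrow(rows), meanlog = -sdl^2 / 2, sdlog = sdl)
  rows$ratio_HL <- 2^true_log2_ratios[rows$protein_id] * noise
  peptides <- data.frame(
    protein_id = rows$protein_id,
    peptide_id = sprintf("%s_%s_p%02d", rows$protein_id, rows$replicate,
                         rows$pep),
    ratio_HL = rows$ratio_HL,
    replicate = rows$replicate,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    protein_id = ids,
    true_log2_ratio = unname(true_log2_ratios),
    true_class = ifelse(true_log2_ratios > 0, "up",
                        ifelse(true_log2_ratios < 0, "down", "unchanged")),
    stringsAsFactors = FALSE
  )
  list(peptides = peptides, truth = truth)
}

#' Simulate the full study
#'
#' Runs every generator branch under one configuration: tRNA references
#' and control/knockdown read sets, the transcriptome, RPF/RNA counts and
#' the SILAC peptide table.
#'
#' @param config A \code{\link{sim_config}}.
#' @param silac Include the SILAC branch (default TRUE).
#' @return A \code{sim_study} list with elements \code{config},
#'   \code{references}, \code{trna_control}, \code{trna_knockdown},
#'   \code{transcriptome}, \code{counts}, \code{silac}.
#' @export
simulate_study <- function(config, silac = TRUE) {
  refs <- simulate_trna_references(config)
  ctrl <- simulate_trna_reads(config, "control", refs = refs)
  kd <- simulate_trna_reads(config, "knockdown", refs = refs)
  tx <- simulate_transcriptome(config)
  cnt <- simulate_counts(config, tx)
  out <- list(config = config, references = refs,
              trna_control = ctrl, trna_knockdown = kd,
              transcriptome = tx, counts = cnt,
              silac = if (silac) simulate_peptides(config) else NULL)
  class(out) <- "sim_study"
  out
}

#' Write a simulated study to disk as pipeline-ready files
#'
#' Emits the file formats the pipeline readers consume: reference FASTA +
#' metadata TSV, one SAM per condition, CDS FASTA, RPF/RNA count TSVs, a
#' replicate-to-condition map, the peptide TSV and truth TSVs.
#'
#' @param study A \code{\link{simulate_study}} result.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_simulation <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  refs <- study$references
  paths <- list(
    reference_fasta = file.path(dir, "trna_reference.fasta"),
    reference_meta = file.path(dir, "trna_reference_meta.tsv"),
    sam_control = file.path(dir, "trna_control.sam"),
    sam_knockdown = file.path(dir, "trna_knockdown.sam"),
    cds_fasta = file.path(dir, "cds.fasta"),
    rpf_counts = file.path(dir, "rpf_counts.tsv"),
    rna_counts = file.path(dir, "rna_counts.tsv"),
    condition_map = file.path(dir, "condition_map.tsv"),
    peptides = file.path(dir, "peptides.tsv"),
    truth_editing = file.path(dir, "truth_editing.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv")
  )
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(refs$mature_sequence,
                                             refs$family_id)),
    paths$reference_fasta)
  fam <- study$config$families
  meta <- data.frame(
    family_id = refs$family_id,
    anticodon = fam$anticodon[match(refs$family_id, fam$family_id)],
    anticodon_start = refs$anticodon_start,
    gene_copies = refs$gene_copies,
    intron_pos = refs$intron_pos
  )
  write_tsv(meta, paths$reference_meta)
  write_sam(study$trna_control$reads, refs, paths$sam_control)
  write_sam(study$trna_knockdown$reads, refs, paths$sam_knockdown)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(study$transcriptome$sequences),
    paths$cds_fasta)
  write_tsv(cbind(gene_id = rownames(study$counts$rpf),
                  as.data.frame(study$counts$rpf)), paths$rpf_counts)
  write_tsv(cbind(gene_id = rownames(study$counts$rna),
                  as.data.frame(study$counts$rna)), paths$rna_counts)
  write_tsv(data.frame(replicate = names(study$counts$condition),
                       condition = unname(study$counts$condition)),
            paths$condition_map)
  if (!is.null(study$silac)) {
    write_tsv(study$silac$peptides, paths$peptides)
  } else {
    paths$peptides <- NULL
  }
  tr <- merge(study$trna_control$truth$rates,
              study$trna_knockdown$truth$rates,
              by = "family_id", suffixes = c("_control", "_knockdown"))
  write_tsv(tr, paths$truth_editing)
  write_tsv(merge(study$transcriptome$truth, study$counts$truth,
                  by = "gene_id"), paths$truth_genes)
  invisible(paths)
}

#' Write alignments as SAM
#'
#' Encodes the package's alignment table as SAM records on the mature
#' references: pre-tRNA flags become 5'/3' soft clips (leader/trailer,
#' with non-CCA clipped bases) or an 8-base insertion (retained intron);
#' mismatch and mapping counts go to the NM and NH tags (NM includes
#' inserted bases, as aligners report it).
#'
#' @param reads A \code{\link{trna_alignments}} table (no deletion gaps).
#' @param refs Matching \code{trna_references}.
#' @param path Output SAM path.
#' @return The path, invisibly.
#' @export
write_sam <- function(reads, refs, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", refs$family_id,
                   nchar(refs$mature_sequence)))
  n <- nrow(reads)
  rl <- reads$end - reads$start + 1L
  cigar <- sprintf("%dM", rl)
  seqs <- reads$seq
  nm <- reads$mismatch_count

  i <- which(reads$covers_leader)
  cigar[i] <- sprintf("4S%dM", rl[i])
  seqs[i] <- paste0("GATT", seqs[i])
  i <- which(reads$covers_trailer)
  cigar[i] <- sprintf("%dM4S", rl[i])
  seqs[i] <- paste0(seqs[i], "TGGA")
  i <- which(reads$covers_intron)
  a <- pmin(10L, rl[i] - 1L)
  cigar[i] <- sprintf("%dM8I%dM", a, rl[i] - a)
  seqs[i] <- paste0(substr(seqs[i], 1L, a), "ACGTACGT",
                    substr(reads$seq[i], a + 1L, rl[i]))
  nm[i] <- nm[i] + 8L

  rec <- sprintf("%s\t0\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*\tNM:i:%d\tNH:i:%d",
                 reads$read_id, reads$family_id, reads$start, cigar, seqs,
                 nm, reads$n_mappings)
  writeLines(c(hdr, rec), path)
  invisible(path)
}
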
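# End-to-end orchestration: config validation, stage composition, and a
# machine-readable run report.

PIPELINE_DEFAULTS <- list(
  max_mismatches = 2L, max_mappings = 50L,
  weighting = "fractional", denominator = "total", min_coverage = 20,
  pseudocount = 0.5, alpha = 0.05, fc = 1.5, te_test = "t",
  min_rna_cpm = 1, adj_alpha = 0.05, log2_cut = 0.5, fdr = "BH",
  protein_test = "moderated", seed = 1L
)

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills defaults, checks parameter
#' ranges and the existence of referenced input files, and aggregates all
#' problems into a single error rather than failing on the first.
#'
#' Recognised input keys (each optional; stages without inputs are
#' skipped): \code{reference_fasta} + \code{reference_meta} +
#' \code{sam_control}/\code{sam_knockdown} (or
#' \code{pileup_control}/\code{pileup_knockdown} TSVs) for the tRNA
#' branch; \code{rpf_counts}, \code{rna_counts}, \code{condition_map} for
#' the ribosome-profiling branch; \code{cds_fasta} for codon usage;
#' \code{peptides} for the SILAC branch; \code{families} to override the
#' built-in family table.
#'
#' @param config Path to a YAML file, or a named list.
#' @param strict Treat unknown keys as errors instead of warnings.
#' @return A validated \code{pipeline_config} list with defaults filled.
#' @export
validate_config <- function(config, strict = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  path_keys <- c("reference_fasta", "reference_meta", "sam_control",
                 "sam_knockdown", "pileup_control", "pileup_knockdown",
                 "rpf_counts", "rna_counts", "condition_map", "cds_fasta",
                 "peptides", "families")
  known <- c(path_keys, names(PIPELINE_DEFAULTS), "outdir")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    msg <- paste("unknown config key(s):", paste(unknown, collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  for (k in names(PIPELINE_DEFAULTS)) {
    if (is.null(config[[k]])) config[[k]] <- PIPELINE_DEFAULTS[[k]]
  }

  errs <- character(0)
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  chk(config$alpha > 0 && config$alpha <= 1,
      sprintf("alpha must be in (0, 1], got %s", config$alpha))
  chk(config$adj_alpha > 0 && config$adj_alpha <= 1,
      sprintf("adj_alpha must be in (0, 1], got %s", config$adj_alpha))
  chk(config$fc >= 1, sprintf("fc must be >= 1, got %s", config$fc))
  chk(config$log2_cut >= 0, "log2_cut must be >= 0")
  chk(config$max_mismatches >= 0, "max_mismatches must be >= 0")
  chk(config$max_mappings >= 1, "max_mappings must be >= 1")
  chk(config$min_coverage >= 0, "min_coverage must be >= 0")
  chk(config$min_rna_cpm >= 0, "min_rna_cpm must be >= 0")
  chk(config$denominator %in% c("total", "ag_only"),
      "denominator must be 'total' or 'ag_only'")
  chk(config$weighting %in% c("fractional", "full"),
      "weighting must be 'fractional' or 'full'")
  chk(config$te_test %in% c("t", "permutation"),
      "te_test must be 't' or 'permutation'")
  chk(config$protein_test %in% c("moderated", "t"),
      "protein_test must be 'moderated' or 't'")
  for (k in intersect(path_keys, names(config))) {
    if (!is.null(config[[k]]) && !file.exists(config[[k]])) {
      errs <- c(errs, sprintf("input file for '%s' not found: %s",
                              k, config[[k]]))
    }
  }
  # paired inputs
  has <- function(k) !is.null(config[[k]])
  if (has("sam_control") != has("sam_knockdown")) {
    errs <- c(errs, "need both sam_control and sam_knockdown (or neither)")
  }
  if ((has("sam_control") || has("pileup_control")) &&
      !(has("reference_fasta") && has("reference_meta"))) {
    errs <- c(errs,
              "tRNA branch needs reference_fasta and reference_meta")
  }
  if (has("rpf_counts") != has("rna_counts")) {
    errs <- c(errs, "need both rpf_counts and rna_counts (or neither)")
  }
  if (has("rpf_counts") && !has("condition_map")) {
    errs <- c(errs, "count tables need a condition_map TSV")
  }
  if (length(errs)) {
    stop("invalid pipeline configuration:\n  - ",
         paste(errs, collapse = "\n  - "))
  }
  class(config) <- c("pipeline_config", "list")
  config
}

#' Run the analysis pipeline
#'
#' Composes the stages end to end on whichever inputs the configuration
#' provides: tRNA editing quantification (filter, wobble pileup, editing
#' rate, abundance; per condition), differential translation efficiency,
#' codon-usage enrichment of the TE classes, and the SILAC protein branch
#' (with its own codon enrichment when CDS sequences are available).
#' Writes per-stage TSV tables plus a JSON run report, and is
#' deterministic given the same inputs and seed.
#'
#' @param config A \code{\link{validate_config}} result (or something it
#'   accepts).
#' @param outdir Output directory (default from the config, else a fresh
#'   temporary directory).
#' @return A \code{run_report} list (also written as
#'   \code{report.json}): per-stage record counts and exclusion tallies,
#'   all stage tables, the config echo and the package version.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  outdir <- outdir %||% config$outdir %||% tempfile("adatseq_run_")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  has <- function(k) !is.null(config[[k]])
  families <- if (has("families")) trna_families(config$families)
              else trna_families()
  table <- build_decoding_table(families)
  write_decoding_table(table, file.path(outdir, "decoding_table.tsv"))

  report <- list(
    package = "adatseq",
    version = as.character(utils::packageVersion("adatseq")),
    seed = config$seed,
    config = unclass(config),
    stages = list()
  )

  # --- tRNA editing branch ---------------------------------------------
  editing <- list()
  if (has("sam_control") || has("pileup_control")) {
    refs <- read_trna_references(config$reference_fasta,
                                 config$reference_meta)
    for (cond in c("control", "knockdown")) {
      sam_key <- paste0("sam_", cond)
      pil_key <- paste0("pileup_", cond)
      if (has(sam_key)) {
        reads <- read_sam_alignments(config[[sam_key]], refs)
        flt <- filter_alignments(reads,
                                 max_mismatches = config$max_mismatches,
                                 max_mappings = config$max_mappings)
        tally <- attr(flt, "exclusion_tally")
        pl <- pileup_at_wobble(flt, refs, weighting = config$weighting)
        ab <- trna_abundance(flt, refs, weighting = config$weighting)
        report$stages[[paste0("trna_", cond)]] <- list(
          n_input = attr(flt, "n_input"), n_retained = nrow(flt),
          exclusions = as.list(tally)
        )
      } else if (has(pil_key)) {
        pl <- read_pileup_tsv(config[[pil_key]])
        ab <- NULL
        report$stages[[paste0("trna_", cond)]] <- list(
          n_input = nrow(pl), n_retained = nrow(pl),
          exclusions = list(pre_trna = 0, mismatches = 0, multimapping = 0)
        )
      } else next
      est <- editing_rate(pl, denominator = config$denominator,
                          min_coverage = config$min_coverage)
      editing[[cond]] <- est
      write_editing_table(est, ab,
                          file.path(outdir,
                                    sprintf("editing_%s.tsv", cond)))
    }
  }

  # --- translation efficiency branch -----------------------------------
  te_res <- NULL
  te_classes <- NULL
  if (has("rpf_counts")) {
    rpf <- read_counts_tsv(config$rpf_counts)
    rna <- read_counts_tsv(config$rna_counts)
    cmap <- read_tsv(config$condition_map)
    condition <- stats::setNames(cmap$condition, cmap$replicate)
    rpf_cpm <- normalize_cpm(rpf)
    rna_cpm <- normalize_cpm(rna)
    te <- translation_efficiency(rpf_cpm, rna_cpm,
                                 pseudocount = config$pseudocount)
    te_res <- differential_te(te, condition,
                              alpha = config$alpha, fc = config$fc,
                              test = config$te_test,
                              rna_cpm = rna_cpm,
                              min_rna_cpm = config$min_rna_cpm)
    write_tsv(as.data.frame(te_res), file.path(outdir, "te_table.tsv"))
    te_classes <- stats::setNames(te_res$te_class, te_res$gene_id)
    report$stages$translatome <- list(
      n_genes = nrow(te_res),
      n_tested = sum(te_res$tested),
      n_excluded_low_expression = sum(!te_res$tested),
      n_up = sum(te_res$te_class == "up"),
      n_down = sum(te_res$te_class == "down"),
      n_unchanged = sum(te_res$te_class == "unchanged")
    )
  } else if (has("sam_control") || has("pileup_control")) {
    report$stages$translatome <- list(
      skipped = "no RPF/RNA count inputs; downstream stages skipped")
  }

  # --- codon usage branch ----------------------------------------------
  te_report <- NULL
  profiles <- NULL
  if (has("cds_fasta")) {
    profiles <- codon_usage_matrix(
      Biostrings::readDNAStringSet(config$cds_fasta))
  }
  if (!is.null(profiles) && !is.null(te_classes) &&
      sum(te_classes == "down") >= 3 && sum(te_classes == "up") >= 3) {
    te_report <- gene_set_report(te_classes, profiles, table = table,
                                 p_adjust = config$fdr)
    write_gene_set_report(te_report, outdir, prefix = "te_codon")
    report$stages$codon_usage <- list(
      n_profiles = nrow(profiles),
      n_down = te_report$n_down, n_up = te_report$n_up,
      n_other = te_report$n_other,
      n_strict_enriched_down_vs_up = sum(
        te_report$down_vs_up$dependency == "strict" &
          te_report$down_vs_up$q_value < 0.05 &
          te_report$down_vs_up$delta > 0, na.rm = TRUE)
    )
  }

  # --- SILAC proteomics branch -----------------------------------------
  prot_res <- NULL
  prot_report <- NULL
  if (has("peptides")) {
    peptides <- read_peptides_tsv(config$peptides)
    ratios <- aggregate_silac(peptides)
    prot_res <- differential_protein(ratios,
                                     adj_alpha = config$adj_alpha,
                                     log2_cut = config$log2_cut,
                                     test = config$protein_test,
                                     p_adjust = config$fdr)
    write_tsv(as.data.frame(prot_res),
              file.path(outdir, "protein_table.tsv"))
    report$stages$proteomics <- list(
      n_proteins = nrow(prot_res),
      n_up = sum(prot_res$protein_class == "up"),
      n_down = sum(prot_res$protein_class == "down"),
      n_unchanged = sum(prot_res$protein_class == "unchanged")
    )
    pclasses <- stats::setNames(prot_res$protein_class, prot_res$protein_id)
    if (!is.null(profiles) &&
        all(names(pclasses) %in% rownames(profiles)) &&
        sum(pclasses == "down") >= 3 && sum(pclasses == "up") >= 3) {
      prot_report <- gene_set_report(pclasses, profiles, table = table,
                                     p_adjust = config$fdr)
      write_gene_set_report(prot_report, outdir, prefix = "protein_codon")
    }
  }

  report$tables <- list(
    decoding_table = as.data.frame(table),
    editing = lapply(editing, as.data.frame),
    te = if (!is.null(te_res)) as.data.frame(te_res),
    te_codon_report = te_report,
    protein = if (!is.null(prot_res)) as.data.frame(prot_res),
    protein_codon_report = prot_report
  )
  report$outdir <- outdir
  jsonlite::write_json(
    report[c("package", "version", "seed", "config", "stages")],
    file.path(outdir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("adatseq pipeline run (seed ", x$seed, ") -> ", x$outdir, "\n",
      sep = "")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat("  ", nm, ": ", sep = "")
    if (!is.null(st$skipped)) {
      cat(st$skipped, "\n")
    } else {
      cat(paste(names(st)[!vapply(st, is.list, logical(1))],
                unlist(st[!vapply(st, is.list, logical(1))]),
                sep = "=", collapse = "  "), "\n")
    }
  }
  invisible(x)
}
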
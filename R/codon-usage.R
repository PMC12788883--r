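# Per-ORF codon usage and ADAT-sensitive codon enrichment tests.

#' Codon usage profile of a single ORF
#'
#' Counts in-frame codons, drops the terminal stop if present, and
#' normalises to relative frequencies over the 61 sense codons.
#'
#' @param orf_sequence In-frame coding sequence (DNA alphabet), starting at
#'   the annotated CDS start; length must be a multiple of 3.
#' @param ambiguous_tol Maximum tolerated fraction of codons containing
#'   non-ACGT characters (default 0); such codons are ignored in counting.
#' @return List with \code{freq} (named numeric over the 61 sense codons,
#'   summing to 1) and \code{n_codons}.
#' @export
#' @examples
#' p <- codon_usage_profile("ATGGCCGCCTAA")
#' p$freq[c("ATG", "GCC")]; p$n_codons
codon_usage_profile <- function(orf_sequence, ambiguous_tol = 0) {
  if (!is.character(orf_sequence) || length(orf_sequence) != 1L ||
      nchar(orf_sequence) == 0L) {
    stop("orf_sequence must be a single non-empty string")
  }
  orf_sequence <- toupper(orf_sequence)
  if (nchar(orf_sequence) %% 3L != 0L) {
    stop("ORF length is not a multiple of 3")
  }
  codons <- split_codons(orf_sequence)
  n <- length(codons)
  if (codons[n] %in% STOP_CODONS) codons <- codons[-n]
  if (length(codons) == 0L) stop("ORF has no sense codons")
  if (any(codons %in% STOP_CODONS)) {
    stop("in-frame internal stop codon at codon position ",
         which(codons %in% STOP_CODONS)[1])
  }
  ambiguous <- !grepl("^[ACGT]{3}$", codons)
  if (mean(ambiguous) > ambiguous_tol) {
    stop("fraction of ambiguous codons (", round(mean(ambiguous), 4),
         ") exceeds tolerance ", ambiguous_tol)
  }
  codons <- codons[!ambiguous]
  counts <- table(factor(codons, levels = sense_codons()))
  freq <- stats::setNames(as.numeric(counts) / length(codons),
                          sense_codons())
  list(freq = freq, n_codons = length(codons))
}

#' Codon usage matrix for a set of ORFs
#'
#' @param sequences Named character vector of ORF sequences (or a
#'   \code{DNAStringSet}).
#' @param ambiguous_tol Passed to \code{\link{codon_usage_profile}}.
#' @return Matrix, genes x 61 sense codons, each row summing to 1, with
#'   attribute \code{n_codons} (named integer vector).
#' @export
codon_usage_matrix <- function(sequences, ambiguous_tol = 0) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (length(sequences) == 0L) stop("no sequences supplied")
  profs <- lapply(sequences, codon_usage_profile,
                  ambiguous_tol = ambiguous_tol)
  m <- do.call(rbind, lapply(profs, `[[`, "freq"))
  rownames(m) <- names(sequences) %||% as.character(seq_along(sequences))
  attr(m, "n_codons") <- vapply(profs, `[[`, integer(1), "n_codons")
  m
}

#' Average codon usage over a set of profiles
#'
#' @param profiles Usage matrix from \code{\link{codon_usage_matrix}}.
#' @param weighting \code{"per_gene"} (default; unweighted mean of per-gene
#'   frequencies) or \code{"per_codon"} (pool codon counts across genes,
#'   weighting genes by length; requires the \code{n_codons} attribute).
#' @return Named numeric vector over the 61 sense codons, summing to 1.
#' @export
global_usage <- function(profiles, weighting = c("per_gene", "per_codon")) {
  weighting <- match.arg(weighting)
  if (is.null(dim(profiles)) || nrow(profiles) == 0L) {
    stop("need at least one profile")
  }
  if (weighting == "per_gene") {
    colMeans(profiles)
  } else {
    n <- attr(profiles, "n_codons")
    if (is.null(n)) stop("per_codon weighting needs the n_codons attribute")
    counts <- profiles * n
    colSums(counts) / sum(counts)
  }
}

#' Per-codon usage change between two gene sets
#'
#' log2 ratio of pseudocount-stabilised mean per-gene frequencies;
#' antisymmetric in its arguments.
#'
#' @param set_a,set_b Usage matrices (genes x 61).
#' @param pseudo_freq Frequency pseudocount (default 1e-4).
#' @return Named numeric vector of log2(mean_a / mean_b) per codon.
#' @export
usage_change <- function(set_a, set_b, pseudo_freq = 1e-4) {
  if (is.null(dim(set_a)) || nrow(set_a) == 0L ||
      is.null(dim(set_b)) || nrow(set_b) == 0L) {
    stop("both gene sets must be non-empty")
  }
  log2((colMeans(set_a) + pseudo_freq) / (colMeans(set_b) + pseudo_freq))
}

#' Codon enrichment test between two gene sets
#'
#' For each of the 61 sense codons, compares per-gene relative frequencies
#' between a focal set (e.g. translationally down-regulated genes) and a
#' comparison set with a two-sided Mann-Whitney (Wilcoxon rank-sum) test —
#' exact when both groups have at most 20 genes and no ties, otherwise the
#' normal approximation with tie correction — followed by BH correction
#' across the 61 codons.  Results are joined to the decoding table's
#' ADAT-dependency annotation.
#'
#' @param focal,comparison Usage matrices (genes x 61 sense codons), at
#'   least 3 genes each.
#' @param table A \code{\link{build_decoding_table}} result.
#' @param pseudo_freq Pseudocount for the log2 usage change (default 1e-4).
#' @param p_adjust Method for \code{\link[stats]{p.adjust}} (default BH).
#' @return A \code{codon_enrichment} data.frame: \code{codon}, \code{aa},
#'   \code{dependency}, \code{adat_sensitive}, \code{mean_focal},
#'   \code{mean_comparison}, \code{delta} (log2 ratio), \code{p_value},
#'   \code{q_value}.
#' @export
codon_enrichment_test <- function(focal, comparison,
                                  table = build_decoding_table(),
                                  pseudo_freq = 1e-4, p_adjust = "BH") {
  if (is.null(dim(focal)) || nrow(focal) < 3L ||
      is.null(dim(comparison)) || nrow(comparison) < 3L) {
    stop("each group needs at least 3 genes")
  }
  codons <- sense_codons()
  stopifnot(identical(colnames(focal), codons),
            identical(colnames(comparison), codons))
  p <- vapply(codons, function(cod) {
    x <- focal[, cod]; y <- comparison[, cod]
    if (all(c(x, y) == c(x, y)[1])) return(1)   # all tied
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- !ties && max(length(x), length(y)) <= 20
    suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided",
                         exact = exact, correct = TRUE)$p.value
    )
  }, numeric(1))
  q <- stats::p.adjust(p, method = p_adjust)
  sensitive <- adat_sensitive_codons(table)
  out <- data.frame(
    codon = codons,
    aa = codon_amino_acid(codons),
    dependency = table$dependency[match(codons, table$codon)],
    adat_sensitive = codons %in% sensitive,
    mean_focal = colMeans(focal),
    mean_comparison = colMeans(comparison),
    delta = usage_change(focal, comparison, pseudo_freq = pseudo_freq),
    p_value = p,
    q_value = q,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("codon_enrichment", "data.frame")
  out
}

#' @export
print.codon_enrichment <- function(x, alpha = 0.05, ...) {
  cat("Codon enrichment test (", nrow(x), "codons )\n")
  sig <- x[!is.na(x$q_value) & x$q_value < alpha & x$delta > 0, ]
  if (nrow(sig)) {
    sig <- sig[order(sig$q_value), ]
    cat("  enriched at q <", alpha, ":",
        paste(sprintf("%s(%s)", sig$codon, sig$dependency), collapse = " "),
        "\n")
  } else {
    cat("  no codon enriched at q <", alpha, "\n")
  }
  invisible(x)
}

#' Gene-set codon enrichment report
#'
#' Runs the codon enrichment procedure for the two standard comparisons of
#' a differential-translation (or differential-protein) analysis:
#' down-regulated vs up-regulated genes, and down-regulated vs all other
#' genes (classified-unchanged plus any unclassified genes present in the
#' profiles, excluding both the down and the up sets).  Also summarises
#' usage change by ADAT-dependency class.
#'
#' @param classes Named character vector (gene -> \code{"up"},
#'   \code{"down"} or \code{"unchanged"}), e.g. from
#'   \code{\link{differential_te}} (\code{te_class} named by gene) or
#'   \code{\link{differential_protein}}.
#' @param profiles Usage matrix covering the classified genes.
#' @param table A \code{\link{build_decoding_table}} result.
#' @param max_missing Maximal tolerated fraction of classified genes
#'   without a profile (default 0.05); beyond it an error lists the genes.
#' @param ... Passed to \code{\link{codon_enrichment_test}}.
#' @return A \code{gene_set_report} list: \code{down_vs_up},
#'   \code{down_vs_all} (both \code{codon_enrichment} tables),
#'   \code{class_summary} (mean delta and significant-codon count per
#'   dependency class, per comparison), and the group sizes.
#' @export
gene_set_report <- function(classes, profiles,
                            table = build_decoding_table(),
                            max_missing = 0.05, ...) {
  stopifnot(!is.null(names(classes)))
  missing <- setdiff(names(classes), rownames(profiles))
  if (length(missing) > max_missing * length(classes)) {
    stop("profiles missing for ", length(missing), " classified genes: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) ", ...")
  }
  classes <- classes[setdiff(names(classes), missing)]
  down <- names(classes)[classes == "down"]
  up <- names(classes)[classes == "up"]
  other <- setdiff(rownames(profiles), c(down, up))

  down_vs_up <- codon_enrichment_test(
    profiles[down, , drop = FALSE], profiles[up, , drop = FALSE],
    table = table, ...)
  down_vs_all <- codon_enrichment_test(
    profiles[down, , drop = FALSE], profiles[other, , drop = FALSE],
    table = table, ...)

  summarise <- function(enr, label) {
    agg <- lapply(split(seq_len(nrow(enr)), enr$dependency), function(i) {
      data.frame(
        comparison = label,
        dependency = enr$dependency[i[1]],
        n_codons = length(i),
        mean_delta = mean(enr$delta[i]),
        n_sig_enriched = sum(enr$q_value[i] < 0.05 & enr$delta[i] > 0,
                             na.rm = TRUE)
      )
    })
    do.call(rbind, agg)
  }
  class_summary <- rbind(summarise(down_vs_up, "down_vs_up"),
                         summarise(down_vs_all, "down_vs_all"))
  rownames(class_summary) <- NULL

  out <- list(
    down_vs_up = down_vs_up,
    down_vs_all = down_vs_all,
    class_summary = class_summary,
    n_down = length(down), n_up = length(up), n_other = length(other)
  )
  class(out) <- "gene_set_report"
  out
}

#' @export
print.gene_set_report <- function(x, ...) {
  cat(sprintf(
    "Gene-set codon enrichment: %d down, %d up, %d other genes\n",
    x$n_down, x$n_up, x$n_other))
  cat("-- down vs up --\n"); print(x$down_vs_up)
  cat("-- down vs all other --\n"); print(x$down_vs_all)
  cat("-- mean log2 usage change by dependency class --\n")
  print(x$class_summary, row.names = FALSE)
  invisible(x)
}

#' Write enrichment tables of a gene-set report to TSV
#'
#' @param report A \code{\link{gene_set_report}} result.
#' @param dir Output directory.
#' @param prefix File-name prefix (default \code{"codon"}).
#' @return Paths of the written files, invisibly.
#' @export
write_gene_set_report <- function(report, dir, prefix = "codon") {
  stopifnot(inherits(report, "gene_set_report"))
  paths <- c(
    file.path(dir, paste0(prefix, "_down_vs_up.tsv")),
    file.path(dir, paste0(prefix, "_down_vs_all.tsv")),
    file.path(dir, paste0(prefix, "_class_summary.tsv"))
  )
  write_tsv(as.data.frame(report$down_vs_up), paths[1])
  write_tsv(as.data.frame(report$down_vs_all), paths[2])
  write_tsv(report$class_summary, paths[3])
  invisible(paths)
}
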
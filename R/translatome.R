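# Translation efficiency from RPF / input-RNA counts, differential
# translation calls, and the SILAC proteomics branch.

#' Counts-per-million normalisation
#'
#' @param counts Non-negative count matrix, genes x replicates.
#' @param pseudocount Added to every count before scaling (default 0; the
#'   TE ratio step has its own pseudocount, keeping CPM sums exact here).
#' @return Matrix of CPM values with the same dimnames.
#' @export
#' @examples
#' m <- matrix(c(10, 90), 2, 1, dimnames = list(c("g1", "g2"), "r1"))
#' normalize_cpm(m)
normalize_cpm <- function(counts, pseudocount = 0) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  libsize <- colSums(counts)
  if (any(libsize == 0)) {
    stop("zero library size in replicate(s): ",
         paste(colnames(counts)[libsize == 0], collapse = ", "))
  }
  sweep(counts + pseudocount, 2, libsize, "/") * 1e6
}

#' Per-gene, per-replicate translation efficiency
#'
#' TE is RPF abundance on the CDS divided by the mRNA abundance of the
#' matched input sample, on CPM scale, with a pseudocount stabilising
#' genes with zero RNA signal:
#' \deqn{TE = (RPF_{cpm} + c) / (RNA_{cpm} + c)}
#'
#' @param rpf_cpm,rna_cpm CPM matrices with identical dimnames (replicate
#'   columns are matched by name).
#' @param pseudocount Default 0.5.
#' @return Matrix of TE values, genes x replicates.
#' @export
#' @examples
#' translation_efficiency(matrix(100, dimnames = list("g", "r")),
#'                        matrix(50, dimnames = list("g", "r")),
#'                        pseudocount = 0)
translation_efficiency <- function(rpf_cpm, rna_cpm, pseudocount = 0.5) {
  rpf_cpm <- as.matrix(rpf_cpm)
  rna_cpm <- as.matrix(rna_cpm)
  if (!identical(rownames(rpf_cpm), rownames(rna_cpm))) {
    stop("RPF and RNA matrices must cover the same genes in the same order")
  }
  if (!identical(sort(colnames(rpf_cpm)), sort(colnames(rna_cpm)))) {
    stop("RPF and RNA matrices must share replicate labels")
  }
  rna_cpm <- rna_cpm[, colnames(rpf_cpm), drop = FALSE]
  (rpf_cpm + pseudocount) / (rna_cpm + pseudocount)
}

#' Differential translation efficiency
#'
#' Per gene, computes the knockdown-vs-control log2 fold change of TE
#' (difference of mean log2 TE) and a two-sided p-value, then classifies
#' genes jointly by effect size and significance: \code{up} when
#' \code{log2fc >= log2(fc)} and \code{p < alpha}, \code{down}
#' symmetrically, otherwise \code{unchanged}.
#'
#' The default test is a pooled-variance Student's t on log2 TE across
#' replicates; \code{test = "permutation"} instead compares the observed t
#' statistic with its distribution over all (or \code{n_perm} sampled)
#' relabelings of the condition vector.  Genes whose mean input-RNA CPM
#' falls below \code{min_rna_cpm} in either condition are excluded from
#' testing (TE is unstable at zero expression); they are reported with
#' \code{tested = FALSE} and class \code{unchanged}.
#'
#' @param te TE matrix from \code{\link{translation_efficiency}}.
#' @param condition Character vector (values \code{"control"} /
#'   \code{"knockdown"}) named by, or ordered as, the columns of \code{te};
#'   at least 2 replicates per condition.
#' @param alpha Significance cut (default 0.05).
#' @param fc Fold-change cut (default 1.5, applied as |log2fc| >= log2(fc)).
#' @param test \code{"t"} (default) or \code{"permutation"}.
#' @param rna_cpm Optional RNA CPM matrix used for the expression floor.
#' @param min_rna_cpm Expression floor (default 1 CPM).
#' @param n_perm Permutations sampled when relabelings are too many to
#'   enumerate (default 1000).
#' @return A \code{te_result} data.frame: \code{gene_id},
#'   \code{te_control}, \code{te_kd} (means over replicates),
#'   \code{log2fc}, \code{p_value}, \code{te_class}, \code{tested}.
#' @export
differential_te <- function(te, condition, alpha = 0.05, fc = 1.5,
                            test = c("t", "permutation"),
                            rna_cpm = NULL, min_rna_cpm = 1,
                            n_perm = 1000L) {
  test <- match.arg(test)
  te <- as.matrix(te)
  condition <- resolve_condition(condition, colnames(te))
  ctrl <- condition == "control"
  kd <- condition == "knockdown"
  if (sum(ctrl) < 2L || sum(kd) < 2L) {
    stop("need at least 2 replicates per condition")
  }
  lt <- log2(te)
  stat <- pooled_t(lt, ctrl, kd)

  p <- 2 * stats::pt(-abs(stat$t), df = stat$df)
  if (test == "permutation") {
    p <- permutation_p(lt, ctrl, kd, stat$t, n_perm)
  }
  # zero within-group variance: no p can be formed; ties stay unchanged
  p[!is.finite(stat$t)] <- NA_real_

  tested <- rep(TRUE, nrow(te))
  if (!is.null(rna_cpm)) {
    rna_cpm <- as.matrix(rna_cpm)[rownames(te), colnames(te), drop = FALSE]
    tested <- rowMeans(rna_cpm[, ctrl, drop = FALSE]) >= min_rna_cpm &
      rowMeans(rna_cpm[, kd, drop = FALSE]) >= min_rna_cpm
  }

  log2fc <- stat$diff
  cls <- rep("unchanged", nrow(te))
  sig <- tested & !is.na(p) & p < alpha
  cls[sig & log2fc >= log2(fc)] <- "up"
  cls[sig & log2fc <= -log2(fc)] <- "down"

  out <- data.frame(
    gene_id = rownames(te) %||% as.character(seq_len(nrow(te))),
    te_control = rowMeans(te[, ctrl, drop = FALSE]),
    te_kd = rowMeans(te[, kd, drop = FALSE]),
    log2fc = log2fc,
    p_value = p,
    te_class = cls,
    tested = tested,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "alpha") <- alpha
  attr(out, "fc") <- fc
  class(out) <- c("te_result", "data.frame")
  out
}

resolve_condition <- function(condition, labels) {
  condition <- as.character(condition)
  if (!is.null(names(condition)) && !is.null(labels)) {
    if (!all(labels %in% names(condition))) {
      stop("condition vector does not name every replicate column")
    }
    condition <- condition[labels]
  }
  bad <- setdiff(unique(condition), c("control", "knockdown"))
  if (length(bad)) {
    stop("condition values must be 'control' or 'knockdown', got: ",
         paste(bad, collapse = ", "))
  }
  condition
}

# vectorised pooled-variance two-sample t on the rows of a matrix
pooled_t <- function(m, ctrl, kd) {
  n1 <- sum(ctrl); n2 <- sum(kd)
  m1 <- rowMeans(m[, ctrl, drop = FALSE])
  m2 <- rowMeans(m[, kd, drop = FALSE])
  v1 <- apply(m[, ctrl, drop = FALSE], 1, stats::var)
  v2 <- apply(m[, kd, drop = FALSE], 1, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = (m2 - m1) / se, diff = m2 - m1, df = n1 + n2 - 2)
}

permutation_p <- function(m, ctrl, kd, t_obs, n_perm) {
  n <- ncol(m)
  n2 <- sum(kd)
  combs <- utils::combn(n, n2)
  if (ncol(combs) > n_perm) {
    combs <- combs[, sample.int(ncol(combs), n_perm), drop = FALSE]
  }
  exceed <- rep(0L, nrow(m))
  for (j in seq_len(ncol(combs))) {
    kd_j <- seq_len(n) %in% combs[, j]
    t_j <- pooled_t(m, !kd_j, kd_j)$t
    exceed <- exceed + (abs(t_j) >= abs(t_obs) - 1e-12 | !is.finite(t_j))
  }
  exceed / ncol(combs)
}

#' @export
print.te_result <- function(x, ...) {
  cat("Differential translation efficiency:", nrow(x), "genes",
      sprintf("(alpha = %g, fold-change cut = %g)\n",
              attr(x, "alpha"), attr(x, "fc")))
  cat(sprintf("  up: %d   down: %d   unchanged: %d   untested: %d\n",
              sum(x$te_class == "up"), sum(x$te_class == "down"),
              sum(x$te_class == "unchanged" & x$tested), sum(!x$tested)))
  invisible(x)
}

#' @export
summary.te_result <- function(object, ...) {
  print(object)
  cat("  median log2 TE fold change:",
      round(stats::median(object$log2fc[object$tested], na.rm = TRUE), 3),
      "\n")
  invisible(object)
}

#' Aggregate SILAC peptide ratios into protein ratios
#'
#' The protein H/L ratio is the arithmetic mean of all peptide ratios
#' assigned to the protein, computed separately per replicate when a
#' \code{replicate} column is present.
#'
#' @param peptides Data.frame with columns \code{protein_id}, \code{ratio}
#'   (H/L, positive) and optionally \code{replicate} and \code{peptide_id}.
#' @return Data.frame \code{protein_id}, \code{replicate},
#'   \code{n_peptides}, \code{ratio}, \code{log2_ratio}.
#' @export
#' @examples
#' aggregate_silac(data.frame(protein_id = "P1", ratio = c(1, 3)))$ratio
aggregate_silac <- function(peptides) {
  if (!"ratio" %in% names(peptides) && "ratio_HL" %in% names(peptides)) {
    names(peptides)[names(peptides) == "ratio_HL"] <- "ratio"
  }
  stopifnot(all(c("protein_id", "ratio") %in% names(peptides)))
  drop <- is.na(peptides$ratio)
  if (any(drop)) {
    bad <- unique(peptides$protein_id[drop])
    warning("dropping ", sum(drop), " peptide(s) without a ratio (",
            paste(utils::head(bad, 5), collapse = ", "), ")")
    peptides <- peptides[!drop, , drop = FALSE]
  }
  if (any(peptides$ratio <= 0)) stop("peptide H/L ratios must be positive")
  if (!"replicate" %in% names(peptides)) peptides$replicate <- "rep1"
  key <- interaction(peptides$protein_id, peptides$replicate, drop = TRUE)
  agg <- data.frame(
    protein_id = tapply(peptides$protein_id, key, `[`, 1),
    replicate = tapply(as.character(peptides$replicate), key, `[`, 1),
    n_peptides = as.integer(tapply(peptides$ratio, key, length)),
    ratio = as.numeric(tapply(peptides$ratio, key, mean)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  agg$log2_ratio <- log2(agg$ratio)
  agg[order(agg$protein_id, agg$replicate), ]
}

#' Differential protein expression from SILAC ratios
#'
#' Tests, per protein, whether the mean log2 H/L ratio across replicates
#' differs from 0, and classifies proteins jointly by effect size and
#' adjusted significance: \code{up} when \code{log2_ratio >= log2_cut} and
#' BH-adjusted p < \code{adj_alpha}; \code{down} symmetrically.  The
#' default test is limma's one-sample moderated t, which shares variance
#' information across proteins (appropriate at n = 3 technical
#' replicates); \code{test = "t"} is a plain one-sample t.
#'
#' @param ratios Output of \code{\link{aggregate_silac}} (one row per
#'   protein x replicate).
#' @param adj_alpha Adjusted-p cut (default 0.05).
#' @param log2_cut Absolute log2 ratio cut (default 0.5).
#' @param test \code{"moderated"} (default) or \code{"t"}.
#' @param p_adjust Multiple-testing method for \code{\link[stats]{p.adjust}}
#'   (default \code{"BH"}).
#' @return A \code{protein_result} data.frame: \code{protein_id},
#'   \code{n_replicates}, \code{log2_ratio}, \code{p_value}, \code{adj_p},
#'   \code{protein_class}.
#' @export
differential_protein <- function(ratios, adj_alpha = 0.05, log2_cut = 0.5,
                                 test = c("moderated", "t"),
                                 p_adjust = "BH") {
  test <- match.arg(test)
  stopifnot(all(c("protein_id", "replicate", "log2_ratio") %in% names(ratios)))
  mat <- tapply(ratios$log2_ratio,
                list(ratios$protein_id, ratios$replicate), mean)
  lr <- rowMeans(mat, na.rm = TRUE)
  n_rep <- rowSums(!is.na(mat))

  if (test == "moderated") {
    fit <- limma::eBayes(limma::lmFit(mat, design = matrix(1, ncol(mat), 1)))
    p <- fit$p.value[, 1]
  } else {
    sdv <- apply(mat, 1, stats::sd, na.rm = TRUE)
    tstat <- lr / (sdv / sqrt(n_rep))
    p <- 2 * stats::pt(-abs(tstat), df = n_rep - 1)
    p[sdv == 0] <- NA_real_   # no within-protein variance: p undefined
  }
  p[n_rep < 2 | !is.finite(p)] <- NA_real_
  adj <- stats::p.adjust(p, method = p_adjust)

  cls <- rep("unchanged", length(lr))
  sig <- !is.na(adj) & adj < adj_alpha
  cls[sig & lr >= log2_cut] <- "up"
  cls[sig & lr <= -log2_cut] <- "down"

  out <- data.frame(
    protein_id = rownames(mat),
    n_replicates = n_rep,
    log2_ratio = unname(lr),
    p_value = unname(p),
    adj_p = unname(adj),
    protein_class = cls,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("protein_result", "data.frame")
  out
}

#' @export
print.protein_result <- function(x, ...) {
  cat("Differential protein expression:", nrow(x), "proteins\n")
  cat(sprintf("  up: %d   down: %d   unchanged: %d\n",
              sum(x$protein_class == "up"), sum(x$protein_class == "down"),
              sum(x$protein_class == "unchanged")))
  invisible(x)
}

#' Read a gene-level count table from TSV
#'
#' First column gene identifiers, remaining columns replicate counts.
#'
#' @param path Path to the TSV.
#' @return Integer matrix, genes x replicates.
#' @export
read_counts_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  if (any(m < 0)) stop("negative counts in ", path)
  m
}

#' Read a SILAC peptide table from TSV
#'
#' Expected columns: \code{protein_id}, \code{peptide_id},
#' \code{ratio_HL}, \code{replicate}.
#'
#' @param path Path to the TSV.
#' @return Data.frame suitable for \code{\link{aggregate_silac}} (the
#'   \code{ratio_HL} column is renamed \code{ratio}).
#' @export
read_peptides_tsv <- function(path) {
  df <- read_tsv(path)
  if ("ratio_HL" %in% names(df)) names(df)[names(df) == "ratio_HL"] <- "ratio"
  stopifnot(all(c("protein_id", "ratio") %in% names(df)))
  df
}
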
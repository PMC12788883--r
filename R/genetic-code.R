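# Genetic-code constants and small shared helpers.

NUCLEOTIDES <- c("A", "C", "G", "T")

STOP_CODONS <- c("TAA", "TAG", "TGA")

ALL_CODONS <- as.vector(outer(outer(NUCLEOTIDES, NUCLEOTIDES, paste0),
                              NUCLEOTIDES, paste0))

#' The 61 sense codons
#'
#' All DNA triplets except the three stop codons, in lexicographic order.
#'
#' @return Character vector of length 61.
#' @export
#' @examples
#' length(sense_codons())
sense_codons <- function() {
  sort(setdiff(ALL_CODONS, STOP_CODONS))
}

# 1-letter -> 3-letter amino acid codes
AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val"
)

# codon -> 3-letter amino acid, standard genetic code (DNA alphabet)
codon_amino_acid <- function(codons) {
  code <- Biostrings::GENETIC_CODE
  one <- code[codons]
  out <- unname(AA_THREE[one])
  out[is.na(one) | one == "*"] <- NA_character_
  out
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# reverse complement of short DNA strings, vectorised
revcomp <- function(x) {
  vapply(strsplit(chartr("ACGT", "TGCA", x), ""),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# split an in-frame sequence into its codons
split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq.int(1L, n - 2L, by = 3L), seq.int(3L, n, by = 3L))
}

#' Wilson score interval for a binomial proportion
#'
#' Closed-form Wilson interval; accepts non-integer successes so that
#' fractionally weighted pileup counts can be used directly.
#'
#' @param x Number of successes (may be fractional).
#' @param n Number of trials (may be fractional), \code{n > 0}.
#' @param conf Confidence level, default 0.95.
#' @return A list with elements \code{low} and \code{high}.
#' @export
#' @examples
#' wilson_interval(40, 100)
wilson_interval <- function(x, n, conf = 0.95) {
  stopifnot(all(n > 0), all(x >= 0), all(x <= n + 1e-9))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

# TSV helpers: plain tab-separated files, no quoting, '.' never mangled
read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
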
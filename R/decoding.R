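# Anticodon -> codon wobble-decoding model and ADAT-dependency classes.

#' Default wobble pairing rules
#'
#' Which codon third bases each wobble-position (position 34) base can pair
#' with.  \code{I} stands for inosine, the product of A-to-I editing: an
#' unedited A34 pairs U only, while I34 pairs A, U and C.  G34 reads C and T
#' (classic wobble), C34 reads G only, and an (unmodified) U34 reads A and G.
#' DNA alphabet is used throughout (T for U).
#'
#' The rule table is data, not code: pass a modified copy to
#' \code{\link{build_decoding_table}} to explore superwobble variants.
#'
#' @return Named list mapping wobble base (\code{A}, \code{C}, \code{G},
#'   \code{T}, \code{I}) to the codon third bases it decodes.
#' @export
#' @examples
#' default_pairing_rules()$I
default_pairing_rules <- function() {
  list(
    A = "T",
    I = c("A", "T", "C"),
    G = c("C", "T"),
    C = "G",
    T = c("A", "G")
  )
}

#' tRNA isoacceptor family table
#'
#' Reads a family table (family_id, amino_acid, anticodon, edited) from a
#' TSV, or returns the default table shipped with the package: the eight
#' ADAT-edited A34 isoacceptor families (Ala-AGC, Arg-ACG, Ile-AAT, Leu-AAG,
#' Pro-AGG, Ser-AGA, Thr-AGT, Val-AAC) plus the standard unedited human
#' cytoplasmic isoacceptor set.  Note that the human set has no G34 family
#' for any of the eight edited boxes, which is what makes their NNC codons
#' strictly dependent on editing.
#'
#' @param path Path to a family TSV; \code{NULL} (default) loads the
#'   built-in table.
#' @return A data.frame with columns \code{family_id}, \code{amino_acid}
#'   (3-letter code), \code{anticodon} (5'->3', DNA alphabet) and
#'   \code{edited} (logical).
#' @export
#' @examples
#' fam <- trna_families()
#' sum(fam$edited)
trna_families <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "trna_families.tsv", package = "adatseq")
  }
  fam <- read_tsv(path)
  required <- c("family_id", "amino_acid", "anticodon", "edited")
  missing <- setdiff(required, names(fam))
  if (length(missing)) {
    stop("family table is missing column(s): ", paste(missing, collapse = ", "))
  }
  fam$edited <- as.logical(as.integer(fam$edited))
  validate_families(fam)
  fam[required]
}

validate_families <- function(families) {
  if (nrow(families) == 0L) return(invisible(families))
  bad <- !grepl("^[ACGT]{3}$", families$anticodon)
  if (any(bad)) {
    stop("invalid anticodon(s) (must be 3-mers over A/C/G/T): ",
         paste(families$family_id[bad], collapse = ", "))
  }
  dup <- duplicated(families$family_id)
  if (any(dup)) {
    stop("duplicate family_id(s): ",
         paste(unique(families$family_id[dup]), collapse = ", "))
  }
  not_a34 <- families$edited & substr(families$anticodon, 1, 1) != "A"
  if (any(not_a34)) {
    stop("edited families must have A at the wobble position (A34): ",
         paste(families$family_id[not_a34], collapse = ", "))
  }
  invisible(families)
}

#' Build the wobble-decoding table
#'
#' Enumerates, for every sense codon, which tRNA families can read it with
#' an unedited wobble base and which can read it only through inosine 34,
#' then classifies each codon's dependence on A-to-I editing:
#' \describe{
#'   \item{strict}{no unedited decoder, at least one I34 decoder — with the
#'     default rules and a G34-free family set these are exactly the NNC
#'     codons of the edited boxes;}
#'   \item{dual}{decodable both with and without editing (e.g. the NNT
#'     codons of edited boxes, read by A34 and by I34);}
#'   \item{independent}{no I34 decoder at all.}
#' }
#'
#' Anticodon positions 35 and 36 pair strict Watson-Crick with codon
#' positions 2 and 1; only position 34 wobbles, according to
#' \code{pairing_rules}.  A family is only credited with codons of its own
#' amino acid, so chemically conceivable but biologically silent pairings
#' (such as an unmodified U34 Ile tRNA formally reading the Met codon) are
#' not recorded.  Stop codons have no tRNA decoders and are excluded.
#'
#' @param families Data.frame as returned by \code{\link{trna_families}};
#'   may be empty.
#' @param pairing_rules Named list, see \code{\link{default_pairing_rules}}.
#' @return A \code{decoding_table} data.frame with one row per sense codon:
#'   \code{codon}, \code{aa}, \code{dependency}, \code{decoders_unedited},
#'   \code{decoders_edited} (comma-separated family ids).
#' @export
#' @examples
#' tab <- build_decoding_table(trna_families())
#' table(tab$dependency)
build_decoding_table <- function(families = trna_families(),
                                 pairing_rules = default_pairing_rules()) {
  validate_families(families)
  codons <- sense_codons()
  unedited <- stats::setNames(vector("list", length(codons)), codons)
  edited <- unedited

  add <- function(sets, codon, id) {
    sets[[codon]] <- c(sets[[codon]], id)
    sets
  }

  for (i in seq_len(nrow(families))) {
    ac <- strsplit(families$anticodon[i], "")[[1]]
    # positions 36 and 35 fix codon positions 1 and 2 (antiparallel pairing)
    stem <- paste0(COMPLEMENT[ac[3]], COMPLEMENT[ac[2]])
    wobble <- ac[1]
    aa <- families$amino_acid[i]
    decode_third <- function(bases) {
      cand <- paste0(stem, bases)
      cand <- cand[!(cand %in% STOP_CODONS)]
      cand[codon_amino_acid(cand) == aa]
    }
    for (cod in decode_third(pairing_rules[[wobble]] %||% character(0))) {
      unedited <- add(unedited, cod, families$family_id[i])
    }
    if (isTRUE(families$edited[i])) {
      for (cod in decode_third(pairing_rules[["I"]] %||% character(0))) {
        edited <- add(edited, cod, families$family_id[i])
      }
    }
  }

  n_un <- lengths(unedited)
  n_ed <- lengths(edited)
  dependency <- ifelse(n_ed == 0L, "independent",
                       ifelse(n_un == 0L, "strict", "dual"))
  tab <- data.frame(
    codon = codons,
    aa = codon_amino_acid(codons),
    dependency = dependency,
    decoders_unedited = vapply(unedited, paste, character(1), collapse = ","),
    decoders_edited = vapply(edited, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- tab$codon
  class(tab) <- c("decoding_table", "data.frame")
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.decoding_table <- function(x, ...) {
  cat("Wobble-decoding table: 61 sense codons\n")
  cnt <- table(factor(x$dependency,
                      levels = c("strict", "dual", "independent")))
  cat(sprintf("  strict (I34-only): %d   dual: %d   independent: %d\n",
              cnt[["strict"]], cnt[["dual"]], cnt[["independent"]]))
  strict <- x$codon[x$dependency == "strict"]
  if (length(strict)) {
    cat("  strict codons:", paste(strict, collapse = " "), "\n")
  }
  invisible(x)
}

#' Classify a codon's dependence on A-to-I tRNA editing
#'
#' @param codon A sense codon (DNA alphabet).
#' @param table A \code{\link{build_decoding_table}} result.
#' @return One of \code{"strict"}, \code{"dual"}, \code{"independent"}.
#' @export
#' @examples
#' tab <- build_decoding_table()
#' classify_codon("GCC", tab)
classify_codon <- function(codon, table) {
  stopifnot(inherits(table, "decoding_table"))
  if (!is.character(codon) || length(codon) != 1L ||
      !grepl("^[ACGT]{3}$", codon)) {
    stop("malformed codon: ", deparse(codon))
  }
  if (codon %in% STOP_CODONS) {
    stop("stop codon ", codon, " has no tRNA decoders")
  }
  table$dependency[match(codon, table$codon)]
}

#' ADAT-sensitive codons
#'
#' Codons read by an ADAT-edited (I34) tRNA — the union of the strict
#' codons and the dual codons that have an I34 decoder.
#'
#' @param table A \code{\link{build_decoding_table}} result.
#' @return Character vector of codons.
#' @export
#' @examples
#' length(adat_sensitive_codons(build_decoding_table()))
adat_sensitive_codons <- function(table) {
  stopifnot(inherits(table, "decoding_table"))
  sort(table$codon[nzchar(table$decoders_edited)])
}

#' Write a decoding table to TSV
#'
#' @param table A \code{decoding_table}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_decoding_table <- function(table, path) {
  stopifnot(inherits(table, "decoding_table"))
  write_tsv(as.data.frame(table), path)
}
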
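# Quantification of A-to-I editing at tRNA position 34 from alignments.
#
# Coordinates are 1-based inclusive on mature tRNA references (no 3' CCA).
# The wobble position of a family is taken from its anticodon_start
# metadata, never from a hardcoded index: variable-length D-loops shift the
# anticodon within the mature sequence.

#' Construct a table of tRNA-seq read alignments
#'
#' The package's canonical alignment container: one row per (read, mapping)
#' with 1-based inclusive coordinates on the mature tRNA reference.
#' \code{seq} holds the read bases projected onto the reference (soft clips
#' and insertions removed, deletions as \code{-}).
#'
#' @param df Data.frame with columns \code{read_id}, \code{family_id},
#'   \code{start}, \code{end}, \code{seq}, \code{mismatch_count},
#'   \code{n_mappings}, \code{covers_leader}, \code{covers_trailer},
#'   \code{covers_intron}.
#' @return A validated \code{trna_alignments} data.frame.
#' @export
trna_alignments <- function(df) {
  required <- c("read_id", "family_id", "start", "end", "seq",
                "mismatch_count", "n_mappings",
                "covers_leader", "covers_trailer", "covers_intron")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("alignment table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df)) {
    stopifnot(all(df$start <= df$end),
              all(df$mismatch_count >= 0),
              all(df$n_mappings >= 1),
              all(nchar(df$seq) == df$end - df$start + 1L))
  }
  df <- as.data.frame(df)[required]
  class(df) <- c("trna_alignments", "data.frame")
  df
}

#' Read mature tRNA references (FASTA + metadata TSV)
#'
#' @param fasta Path to a FASTA of mature tRNA sequences (no 3' CCA), one
#'   record per isodecoder family, names matching \code{family_id}.
#' @param metadata Path to a TSV with columns \code{family_id},
#'   \code{anticodon_start} (1-based position of anticodon position 1, i.e.
#'   the wobble position) and optionally \code{anticodon},
#'   \code{gene_copies}, \code{intron_pos} (position after which intronic
#'   sequence would be inserted; NA when intronless).
#' @return A \code{trna_references} data.frame with columns
#'   \code{family_id}, \code{mature_sequence}, \code{anticodon_start},
#'   \code{gene_copies}, \code{intron_pos}.
#' @export
read_trna_references <- function(fasta, metadata) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  meta <- read_tsv(metadata)
  if (!all(c("family_id", "anticodon_start") %in% names(meta))) {
    stop("reference metadata must have family_id and anticodon_start columns")
  }
  idx <- match(meta$family_id, names(seqs))
  if (anyNA(idx)) {
    stop("families in metadata absent from FASTA: ",
         paste(meta$family_id[is.na(idx)], collapse = ", "))
  }
  refs <- data.frame(
    family_id = meta$family_id,
    mature_sequence = as.character(seqs)[idx],
    anticodon_start = as.integer(meta$anticodon_start),
    gene_copies = if ("gene_copies" %in% names(meta))
      as.integer(meta$gene_copies) else 1L,
    intron_pos = if ("intron_pos" %in% names(meta))
      suppressWarnings(as.integer(meta$intron_pos)) else NA_integer_,
    stringsAsFactors = FALSE
  )
  len <- nchar(refs$mature_sequence)
  bad <- refs$anticodon_start < 1L | refs$anticodon_start > len - 2L
  if (any(bad)) {
    stop("anticodon_start outside reference for: ",
         paste(refs$family_id[bad], collapse = ", "))
  }
  if ("anticodon" %in% names(meta)) {
    obs <- substr(refs$mature_sequence, refs$anticodon_start,
                  refs$anticodon_start + 2L)
    # edited families are annotated with an A34 anticodon; the reference
    # carries the genomic (unedited) base, so this must match exactly
    mism <- obs != meta$anticodon
    if (any(mism)) {
      stop("reference sequence does not carry the annotated anticodon for: ",
           paste(refs$family_id[mism], collapse = ", "))
    }
  }
  class(refs) <- c("trna_references", "data.frame")
  refs
}

#' Read tRNA-seq alignments from a SAM file
#'
#' Parses a SAM of reads aligned to mature tRNA references (e.g. Bowtie
#' output).  Mismatch counts come from the NM tag (minus inserted/deleted
#' bases, so indels are not double-counted), multimapping from the NH tag.
#' Pre-tRNA evidence is derived from the alignment itself:
#' \itemize{
#'   \item a 5' soft clip on a read starting at reference position 1 is a
#'     leader overhang (\code{covers_leader});
#'   \item a 3' soft clip on a read ending at the reference 3' end is a
#'     trailer overhang (\code{covers_trailer}) — unless the clipped bases
#'     are a prefix of the post-transcriptionally added CCA tail, which is
#'     not genomic trailer sequence;
#'   \item an insertion of \code{min_intron} or more bases is retained
#'     intronic sequence (\code{covers_intron}).
#' }
#'
#' @param sam Path to a SAM file.
#' @param refs \code{trna_references} for coordinate validation.
#' @param min_intron Minimum insertion length called as intronic (default 4).
#' @return A \code{\link{trna_alignments}} data.frame.
#' @export
read_sam_alignments <- function(sam, refs, min_intron = 4L) {
  bam <- Rsamtools::asBam(sam,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "cigar", "seq"),
    tag = c("NM", "NH")
  )
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(rec$pos)
  qname <- rec$qname[keep]
  rname <- as.character(rec$rname)[keep]
  pos <- rec$pos[keep]
  cigar <- rec$cigar[keep]
  seq <- as.character(rec$seq)[keep]
  nm <- (rec$tag$NM %||% rep(0L, length(rec$qname)))[keep]
  nh <- (rec$tag$NH %||% rep(1L, length(rec$qname)))[keep]
  nm[is.na(nm)] <- 0L
  nh[is.na(nh)] <- 1L

  n <- length(qname)
  out <- vector("list", n)
  ref_len <- stats::setNames(nchar(refs$mature_sequence), refs$family_id)
  aligned_seq <- character(n)
  end <- integer(n)
  lead <- trail <- intr <- logical(n)
  mism <- integer(n)

  for (i in seq_len(n)) {
    ops <- cigar_ops(cigar[i])
    read_seq <- seq[i]
    rpos <- 1L   # cursor in read
    ref_consumed <- 0L
    pieces <- character(0)
    clip5 <- 0L
    clip3 <- 0L
    clip3_seq <- ""
    ins_total <- 0L
    del_total <- 0L
    first_op <- TRUE
    for (j in seq_len(nrow(ops))) {
      op <- ops$op[j]; len <- ops$len[j]
      if (op == "S") {
        if (first_op) clip5 <- len
        else {
          clip3 <- len
          clip3_seq <- substr(read_seq, rpos, rpos + len - 1L)
        }
        rpos <- rpos + len
      } else if (op %in% c("M", "=", "X")) {
        pieces <- c(pieces, substr(read_seq, rpos, rpos + len - 1L))
        rpos <- rpos + len
        ref_consumed <- ref_consumed + len
      } else if (op == "I") {
        ins_total <- ins_total + len
        if (len >= min_intron) intr[i] <- TRUE
        rpos <- rpos + len
      } else if (op %in% c("D", "N")) {
        pieces <- c(pieces, strrep("-", len))
        ref_consumed <- ref_consumed + len
        del_total <- del_total + len
      } else if (op == "H") {
        if (first_op) clip5 <- len else clip3 <- len
      }
      first_op <- FALSE
    }
    aligned_seq[i] <- paste(pieces, collapse = "")
    end[i] <- pos[i] + ref_consumed - 1L
    L <- ref_len[[rname[i]]]
    if (is.null(L)) stop("read aligned to unknown family: ", rname[i])
    if (end[i] > L) stop("read ", qname[i], " extends past reference ",
                         rname[i])
    lead[i] <- clip5 > 0L && pos[i] == 1L
    cca_ok <- clip3 <= 3L && clip3_seq == substr("CCA", 1L, clip3)
    trail[i] <- clip3 > 0L && end[i] == L && !cca_ok
    mism[i] <- max(0L, nm[i] - ins_total - del_total)
  }

  trna_alignments(data.frame(
    read_id = qname, family_id = rname, start = pos, end = end,
    seq = aligned_seq, mismatch_count = mism, n_mappings = nh,
    covers_leader = lead, covers_trailer = trail, covers_intron = intr,
    stringsAsFactors = FALSE
  ))
}

cigar_ops <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  data.frame(
    len = as.integer(sub("[A-Z=]$", "", toks)),
    op = sub("^\\d+", "", toks),
    stringsAsFactors = FALSE
  )
}

#' Filter tRNA-seq alignments
#'
#' Retains reads with at most \code{max_mismatches} mismatches and at most
#' \code{max_mappings} reported mappings, and excludes pre-tRNA reads
#' (those carrying 5' leader, 3' trailer or intronic sequence).  Exclusion
#' reasons are tallied with precedence pre_trna > mismatches > multimapping,
#' so every input read is accounted for exactly once.
#'
#' @param reads A \code{\link{trna_alignments}} table.
#' @param max_mismatches Maximum mismatches retained (default 2).
#' @param max_mappings Maximum number of mappings retained (default 50).
#' @return The retained \code{trna_alignments}, with attributes
#'   \code{exclusion_tally} (named vector: pre_trna, mismatches,
#'   multimapping) and \code{n_input}.
#' @export
#' @examples
#' \dontrun{flt <- filter_alignments(reads); attr(flt, "exclusion_tally")}
filter_alignments <- function(reads, max_mismatches = 2L, max_mappings = 50L) {
  if (max_mismatches < 0 || max_mappings < 1) {
    stop("max_mismatches must be >= 0 and max_mappings >= 1")
  }
  stopifnot(inherits(reads, "trna_alignments") || is.data.frame(reads))
  pre <- reads$covers_leader | reads$covers_trailer | reads$covers_intron
  mm <- !pre & reads$mismatch_count > max_mismatches
  mult <- !pre & !mm & reads$n_mappings > max_mappings
  keep <- !(pre | mm | mult)
  out <- trna_alignments(reads[keep, , drop = FALSE])
  attr(out, "exclusion_tally") <- c(
    pre_trna = sum(pre), mismatches = sum(mm), multimapping = sum(mult)
  )
  attr(out, "n_input") <- nrow(reads)
  out
}

#' Pile up read bases at the wobble position
#'
#' For each family, sums read weights by the base observed at the wobble
#' position (anticodon position 1, from reference metadata).  Reads not
#' spanning the position, or showing a deletion there, contribute nothing.
#' With \code{weighting = "fractional"} (default) each mapping of a read
#' contributes 1/n_mappings, avoiding double counting of multimappers.
#'
#' @param reads Filtered \code{\link{trna_alignments}}.
#' @param refs \code{trna_references}.
#' @param weighting \code{"fractional"} or \code{"full"}.
#' @return A \code{wobble_pileup} data.frame: \code{family_id}, weighted
#'   counts \code{A}, \code{C}, \code{G}, \code{T}, and \code{coverage}.
#' @export
pileup_at_wobble <- function(reads, refs,
                             weighting = c("fractional", "full")) {
  weighting <- match.arg(weighting)
  unknown <- setdiff(unique(reads$family_id), refs$family_id)
  if (length(unknown)) {
    stop("reads aligned to families absent from references: ",
         paste(unknown, collapse = ", "))
  }
  ridx <- match(reads$family_id, refs$family_id)
  ref_len <- nchar(refs$mature_sequence)[ridx]
  if (nrow(reads) && any(reads$start < 1L | reads$end > ref_len)) {
    stop("read coordinates outside the mature reference")
  }
  wob <- refs$anticodon_start[ridx]
  spans <- nrow(reads) > 0 & reads$start <= wob & reads$end >= wob
  base <- substr(reads$seq, wob - reads$start + 1L, wob - reads$start + 1L)
  ok <- spans & base %in% NUCLEOTIDES
  w <- if (weighting == "fractional") 1 / reads$n_mappings else
    rep(1, nrow(reads))

  counts <- matrix(0, nrow = nrow(refs), ncol = 4,
                   dimnames = list(refs$family_id, NUCLEOTIDES))
  if (any(ok)) {
    agg <- tapply(w[ok], list(reads$family_id[ok], base[ok]), sum)
    counts[rownames(agg), colnames(agg)] <-
      ifelse(is.na(agg), 0, agg)
  }
  out <- data.frame(family_id = refs$family_id, counts,
                    coverage = rowSums(counts),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("wobble_pileup", "data.frame")
  out
}

#' Read a precomputed wobble pileup from TSV
#'
#' Dialect: tab-separated with header; required columns \code{family_id},
#' \code{A}, \code{C}, \code{G}, \code{T}; an optional \code{pos} column
#' (the wobble coordinate) is carried through but not interpreted.  This
#' bypasses alignment parsing entirely.
#'
#' @param path Path to the pileup TSV.
#' @return A \code{wobble_pileup} data.frame.
#' @export
read_pileup_tsv <- function(path) {
  df <- read_tsv(path)
  need <- c("family_id", NUCLEOTIDES)
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("pileup TSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(df[NUCLEOTIDES] < 0)) stop("negative base counts in pileup TSV")
  out <- df[c("family_id", NUCLEOTIDES, intersect("pos", names(df)))]
  out$coverage <- rowSums(out[NUCLEOTIDES])
  class(out) <- c("wobble_pileup", "data.frame")
  out
}

#' Estimate per-family A-to-I editing rates
#'
#' The editing rate is the fraction of G calls at the wobble position:
#' inosine is read as guanosine by reverse transcription, so at an A34
#' position the G allele fraction measures editing.  With
#' \code{denominator = "total"} (default) the rate is G/(A+C+G+T), keeping
#' C/T sequencing errors in the denominator; \code{"ag_only"} uses G/(A+G).
#' A 95\% Wilson score interval is attached.
#'
#' @param pileup A \code{wobble_pileup}.
#' @param denominator \code{"total"} or \code{"ag_only"}.
#' @param min_coverage Families below this coverage are flagged
#'   \code{"insufficient_coverage"} and get no estimate (default 20).
#' @param conf Confidence level for the Wilson interval.
#' @return An \code{editing_estimates} data.frame: \code{family_id},
#'   counts, \code{coverage}, \code{rate}, \code{ci_low}, \code{ci_high},
#'   \code{flag}.
#' @export
#' @examples
#' pl <- data.frame(family_id = "tRNA-Val-AAC", A = 60, C = 0, G = 40, T = 0,
#'                  coverage = 100)
#' class(pl) <- c("wobble_pileup", "data.frame")
#' editing_rate(pl)$rate
editing_rate <- function(pileup, denominator = c("total", "ag_only"),
                         min_coverage = 20, conf = 0.95) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(pileup, "wobble_pileup") || is.data.frame(pileup))
  g <- pileup$G
  denom <- if (denominator == "total") pileup$coverage else
    pileup$A + pileup$G
  ok <- pileup$coverage >= min_coverage & denom > 0
  rate <- ci_low <- ci_high <- rep(NA_real_, nrow(pileup))
  if (any(ok)) {
    rate[ok] <- g[ok] / denom[ok]
    ci <- wilson_interval(g[ok], denom[ok], conf = conf)
    ci_low[ok] <- ci$low
    ci_high[ok] <- ci$high
  }
  out <- data.frame(
    family_id = pileup$family_id,
    A = pileup$A, C = pileup$C, G = pileup$G, T = pileup$T,
    coverage = pileup$coverage,
    rate = rate, ci_low = ci_low, ci_high = ci_high,
    flag = ifelse(ok, "", "insufficient_coverage"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("editing_estimates", "data.frame")
  out
}

#' @export
print.editing_estimates <- function(x, digits = 3, ...) {
  cat("A-to-I editing estimates (position 34) for", nrow(x), "families\n")
  df <- data.frame(family_id = x$family_id,
                   coverage = round(x$coverage, 1),
                   rate = round(x$rate, digits),
                   ci = ifelse(is.na(x$rate), "-",
                               sprintf("[%.*f, %.*f]", digits, x$ci_low,
                                       digits, x$ci_high)),
                   flag = x$flag)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Steady-state tRNA abundance (reads per million)
#'
#' @param reads Filtered \code{\link{trna_alignments}}.
#' @param refs Optional \code{trna_references}; families without reads are
#'   then reported with zero abundance.
#' @param weighting \code{"fractional"} (default) or \code{"full"};
#'   fractional weighting counts each read once across its mappings.
#' @return Data.frame \code{family_id}, \code{weighted_count}, \code{rpm};
#'   \code{rpm} sums to 1e6.
#' @export
trna_abundance <- function(reads, refs = NULL,
                           weighting = c("fractional", "full")) {
  weighting <- match.arg(weighting)
  if (nrow(reads) == 0L) stop("no retained reads: abundance undefined")
  w <- if (weighting == "fractional") 1 / reads$n_mappings else
    rep(1, nrow(reads))
  fam <- if (!is.null(refs)) refs$family_id else
    sort(unique(reads$family_id))
  cnt <- tapply(w, factor(reads$family_id, levels = fam), sum)
  cnt[is.na(cnt)] <- 0
  data.frame(
    family_id = fam,
    weighted_count = as.numeric(cnt),
    rpm = 1e6 * as.numeric(cnt) / sum(cnt),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write the per-family editing/abundance table to TSV
#'
#' @param estimates An \code{editing_estimates} table.
#' @param abundance Optional abundance table from \code{\link{trna_abundance}}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_editing_table <- function(estimates, abundance = NULL, path) {
  df <- as.data.frame(estimates)
  if (!is.null(abundance)) {
    df <- merge(df, abundance, by = "family_id", all.x = TRUE, sort = FALSE)
  }
  write_tsv(df, path)
}
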
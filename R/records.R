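#' editscan: mismatch-cluster scanning for editing and artifact signatures
#'
#' Scans capillary sequencing traces placed on a reference genome for runs of
#' same-type mismatches, separates the systematic dye sub-peak G-to-A
#' base-calling artifact from ADAR (A-to-I) and APOBEC editing candidates via
#' phred-quality enrichment, and quantifies enrichment with exact statistics.
#' A seeded simulator provides cohorts with known truth for every stage.
#'
#' @section Pipeline:
#' \enumerate{
#'   \item \code{\link{simulate_cohort}} (or external FASTA/QUAL input)
#'   \item \code{\link{place_traces}} / \code{\link{classify_placement}}
#'   \item \code{\link{enumerate_mismatches}}, \code{\link{find_runs}}
#'   \item \code{\link{select_enriched}}, \code{\link{tally_by_type}}
#'   \item \code{\link{motif_artifact_flag}}, \code{\link{offset_artifact_test}}
#'   \item \code{\link{fisher_exact_two_sided}} and friends
#' }
#'
#' @keywords internal
"_PACKAGE"

## The 12 ordered base substitutions, read orientation.
MISMATCH_TYPES <- c(
  "A>C", "A>G", "A>T",
  "C>A", "C>G", "C>T",
  "G>A", "G>C", "G>T",
  "T>A", "T>C", "T>G"
)

EDITING_TYPES <- c("G>A", "C>T", "A>G", "T>C")

#' Construct a sequencing trace record
#'
#' A trace is a single capillary read: its base calls, optional per-base phred
#' quality scores, and archive metadata (sequencing center, organism, and the
#' likely molecular origin of the template, DNA or RNA).
#'
#' @param trace_id character scalar, unique identifier.
#' @param sequence character scalar over \code{A,C,G,T,N}; other letters are
#'   mapped to \code{N}.
#' @param quals optional integer vector of phred scores, one per base,
#'   each in \code{[0, 93]}.
#' @param origin \code{"DNA"}, \code{"RNA"} or \code{"UNKNOWN"}.
#' @param center sequencing center label.
#' @param organism organism label.
#' @return An object of class \code{trace_read}.
#' @export
trace_read <- function(trace_id, sequence, quals = NULL,
                       origin = "UNKNOWN", center = "unknown",
                       organism = "unknown") {
  stopifnot(is.character(trace_id), length(trace_id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- clean_seq(sequence)
  if (!is.null(quals)) {
    quals <- as.integer(quals)
    if (length(quals) != nchar(sequence))
      stop("trace '", trace_id, "': ", length(quals),
           " quality scores for ", nchar(sequence), " bases", call. = FALSE)
    if (anyNA(quals) || any(quals < 0L | quals > 93L))
      stop("trace '", trace_id, "': phred scores must be integers in [0, 93]",
           call. = FALSE)
  }
  origin <- match.arg(origin, c("DNA", "RNA", "UNKNOWN"))
  structure(
    list(trace_id = trace_id, sequence = sequence, quals = quals,
         origin = origin, center = center, organism = organism),
    class = "trace_read"
  )
}

#' @export
print.trace_read <- function(x, ...) {
  cat(sprintf("<trace_read> %s: %d bp, origin %s, center %s%s\n",
              x$trace_id, nchar(x$sequence), x$origin, x$center,
              if (is.null(x$quals)) ", no quals" else ""))
  invisible(x)
}

#' @export
length.trace_read <- function(x) nchar(x$sequence)

#' Construct a reference genome
#'
#' @param sequences named character vector, one uppercase \code{A,C,G,T,N}
#'   string per reference sequence; other letters are mapped to \code{N}.
#' @return An object of class \code{reference_genome}: a named character
#'   vector with a \code{lengths} attribute. All positions in the package are
#'   0-based, intervals half-open.
#' @export
reference_genome <- function(sequences) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)) ||
      any(!nzchar(names(sequences))))
    stop("reference sequences must have unique non-empty names", call. = FALSE)
  sequences <- vapply(sequences, clean_seq, character(1))
  structure(sequences, lengths = nchar(sequences), class = "reference_genome")
}

#' @export
print.reference_genome <- function(x, ...) {
  cat(sprintf("<reference_genome> %d sequence(s), %s bp total\n",
              length(unclass(x)), format(sum(attr(x, "lengths")),
                                         big.mark = ",")))
  invisible(x)
}

## uppercase and collapse anything outside ACGTN to N
clean_seq <- function(s) {
  s <- toupper(s)
  if (grepl("[^ACGTN]", s)) s <- gsub("[^ACGTN]", "N", s)
  s
}

#' Fetch a reference slice
#'
#' @param ref a \code{\link{reference_genome}}.
#' @param chrom sequence name.
#' @param start,end 0-based half-open interval; clipped to the sequence.
#' @return character scalar.
#' @export
ref_fetch <- function(ref, chrom, start, end) {
  seqs <- unclass(ref)
  if (!chrom %in% names(seqs)) stop("unknown reference sequence: ", chrom,
                                    call. = FALSE)
  L <- nchar(seqs[[chrom]])
  start <- max(0L, start); end <- min(L, end)
  if (end <= start) return("")
  substr(seqs[[chrom]], start + 1L, end)
}

#' Reverse-complement a nucleotide string
#'
#' \code{N} maps to \code{N}.
#' @param s character scalar over \code{A,C,G,T,N}.
#' @return character scalar.
#' @export
revcomp <- function(s) {
  if (!nzchar(s)) return(s)
  chartr("ACGTN", "TGCAN", rawToChar(rev(charToRaw(s))))
}

## complement without reversal, vectorised over single characters
comp_chars <- function(x) chartr("ACGTN", "TGCAN", x)

## split a string into single characters
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
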
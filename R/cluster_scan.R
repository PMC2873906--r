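## Mismatch enumeration on accepted placements and detection of same-type
## runs, with the motif-uniformity, span and N filters.

#' Scan configuration
#'
#' @param min_run minimum run length: 5 for the motif survey, 3 for the
#'   quality-enriched sets.
#' @param min_span_bp minimum distance (trace coordinates) between the first
#'   and last mismatch of a run.
#' @param motif_uniform require all members of a run to share the same 3-bp
#'   trace motif.
#' @param drop_n_context drop runs containing a mismatch whose 3-bp context
#'   contains \code{N} (or lies at a read end).
#' @return list of class \code{scan_config}.
#' @export
scan_config <- function(min_run = 5L, min_span_bp = 100L,
                        motif_uniform = FALSE, drop_n_context = TRUE) {
  stopifnot(min_run >= 1L, min_span_bp >= 0L)
  structure(list(min_run = as.integer(min_run),
                 min_span_bp = as.integer(min_span_bp),
                 motif_uniform = isTRUE(motif_uniform),
                 drop_n_context = isTRUE(drop_n_context)),
            class = "scan_config")
}

#' Enumerate mismatches on an accepted placement
#'
#' Walks the ungapped alignment column by column and reports every column
#' where trace and reference differ and neither base is \code{N}. All fields
#' are reported in read orientation: for minus-strand placements the
#' reference base (and the reference 3-mer) is reverse-complemented, so a
#' reference \code{C} aligned to a trace \code{A} yields type \code{G>A}.
#' Phred scores are attached from the trace when present.
#'
#' @param aln one accepted placement row (UNIQUE, ungapped).
#' @param reference a \code{\link{reference_genome}}.
#' @param trace the \code{\link{trace_read}} behind the placement.
#' @return data frame sorted by \code{trace_pos} with columns
#'   \code{trace_id}, \code{chrom}, \code{ref_pos}, \code{trace_pos},
#'   \code{ref_base}, \code{trace_base}, \code{type}, \code{qual},
#'   \code{trace_motif}, \code{ref_motif}, \code{strand}.
#' @export
enumerate_mismatches <- function(aln, reference, trace) {
  stopifnot(nrow(aln) == 1L, !aln$gapped,
            aln$ref_end - aln$ref_start == aln$trace_end - aln$trace_start)
  chromseq <- unclass(reference)[[aln$chrom]]
  if (is.null(chromseq) || aln$ref_start < 0L || aln$ref_end > nchar(chromseq))
    stop("placement coordinates outside reference (corrupt alignment)",
         call. = FALSE)
  refwin <- substr(chromseq, aln$ref_start + 1L, aln$ref_end)
  read <- trace$sequence
  L <- nchar(read)
  minus <- aln$strand == "-"
  s <- if (minus) revcomp(read) else read
  ## s-coordinates of the aligned query window
  q0 <- if (minus) L - aln$trace_end else aln$trace_start
  q1 <- if (minus) L - aln$trace_start else aln$trace_end
  qwin <- substr(s, q0 + 1L, q1)
  a <- charToRaw(refwin)
  b <- charToRaw(qwin)
  nN <- charToRaw("N")
  diff <- which(a != b & a != nN & b != nN)
  if (length(diff) == 0L) return(empty_mismatch_df())
  i <- diff - 1L                       # 0-based offset within window
  ref_pos <- aln$ref_start + i
  if (minus) {
    trace_pos <- L - 1L - (q0 + i)
    ref_base <- comp_chars(rawToChar(a[diff], multiple = TRUE))
    trace_base <- comp_chars(rawToChar(b[diff], multiple = TRUE))
  } else {
    trace_pos <- q0 + i
    ref_base <- rawToChar(a[diff], multiple = TRUE)
    trace_base <- rawToChar(b[diff], multiple = TRUE)
  }
  qual <- if (is.null(trace$quals)) rep(NA_integer_, length(diff))
          else trace$quals[trace_pos + 1L]
  trace_motif <- motif_at(read, trace_pos)
  gmot <- motif_at(chromseq, ref_pos)
  ref_motif <- if (minus) vapply(gmot, revcomp, character(1), USE.NAMES = FALSE)
               else gmot
  out <- data.frame(
    trace_id = trace$trace_id, chrom = aln$chrom,
    ref_pos = ref_pos, trace_pos = trace_pos,
    ref_base = ref_base, trace_base = trace_base,
    type = paste0(ref_base, ">", trace_base),
    qual = qual, trace_motif = trace_motif, ref_motif = ref_motif,
    strand = aln$strand, stringsAsFactors = FALSE)
  out[order(out$trace_pos), , drop = FALSE]
}

## 3-mer centred on each 0-based position; positions without a full 3-mer
## inside the sequence yield "N"-padded motifs (treated as N-context).
motif_at <- function(seq, pos) {
  L <- nchar(seq)
  left <- ifelse(pos >= 1L, substring(seq, pos, pos), "N")
  mid <- substring(seq, pos + 1L, pos + 1L)
  right <- ifelse(pos + 2L <= L, substring(seq, pos + 2L, pos + 2L), "N")
  paste0(left, mid, right)
}

empty_mismatch_df <- function() {
  data.frame(trace_id = character(0), chrom = character(0),
             ref_pos = integer(0), trace_pos = integer(0),
             ref_base = character(0), trace_base = character(0),
             type = character(0), qual = integer(0),
             trace_motif = character(0), ref_motif = character(0),
             strand = character(0), stringsAsFactors = FALSE)
}

#' Detect same-type mismatch runs
#'
#' A run is a maximal block of consecutive mismatches of one substitution
#' type along the trace: matching columns between members do not break a run,
#' any mismatch of a different type does. "Consecutive" refers to the ordered
#' mismatch list, not to adjacent bases. Runs shorter than
#' \code{cfg$min_run} are dropped; every mismatch belongs to exactly one
#' maximal run before that threshold is applied.
#'
#' @param mismatches mismatch table (one or more traces); grouped by
#'   \code{trace_id} and ordered by \code{trace_pos} internally.
#' @param cfg a \code{\link{scan_config}}.
#' @return data frame of runs with columns \code{trace_id}, \code{type},
#'   \code{length}, \code{span_bp}, \code{first_pos}, \code{last_pos} and a
#'   list-column \code{members} holding each run's mismatch rows.
#' @export
find_runs <- function(mismatches, cfg = scan_config()) {
  if (nrow(mismatches) == 0L) return(empty_run_df())
  out <- list()
  for (id in unique(mismatches$trace_id)) {
    mm <- mismatches[mismatches$trace_id == id, , drop = FALSE]
    mm <- mm[order(mm$trace_pos), , drop = FALSE]
    r <- rle(mm$type)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$lengths >= cfg$min_run)
    for (k in keep) {
      members <- mm[starts[[k]]:ends[[k]], , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        trace_id = id, type = r$values[[k]],
        length = r$lengths[[k]],
        span_bp = members$trace_pos[[nrow(members)]] - members$trace_pos[[1L]],
        first_pos = members$trace_pos[[1L]],
        last_pos = members$trace_pos[[nrow(members)]],
        stringsAsFactors = FALSE)
      out[[length(out)]]$members <- I(list(members))
    }
  }
  if (length(out) == 0L) return(empty_run_df())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_run_df <- function() {
  d <- data.frame(trace_id = character(0), type = character(0),
                  length = integer(0), span_bp = integer(0),
                  first_pos = integer(0), last_pos = integer(0),
                  stringsAsFactors = FALSE)
  d$members <- I(list())
  d
}

#' Keep runs spanning at least \code{min_span_bp}
#'
#' Span is the trace-coordinate distance between the first and last mismatch
#' of the run (identical to the reference-coordinate span for ungapped
#' placements). A pure, idempotent filter.
#'
#' @param runs run table from \code{\link{find_runs}}.
#' @param cfg a \code{\link{scan_config}}.
#' @return filtered run table.
#' @export
apply_span_filter <- function(runs, cfg = scan_config()) {
  runs[runs$span_bp >= cfg$min_span_bp, , drop = FALSE]
}

#' Keep runs whose members share one 3-bp trace motif
#'
#' All members must carry the identical trace 3-mer (the reference 3-mer is
#' then necessarily uniform too, the run being a single substitution type).
#' When \code{cfg$drop_n_context}, runs containing any member whose trace or
#' reference motif contains \code{N} (including read-edge mismatches) are
#' dropped whole.
#'
#' @param runs run table from \code{\link{find_runs}}.
#' @param cfg a \code{\link{scan_config}}.
#' @return filtered run table.
#' @export
apply_motif_filter <- function(runs, cfg = scan_config()) {
  if (nrow(runs) == 0L) return(runs)
  keep <- vapply(runs$members, function(m) {
    has_n <- grepl("N", m$trace_motif, fixed = TRUE) |
             grepl("N", m$ref_motif, fixed = TRUE)
    if (cfg$drop_n_context && any(has_n)) return(FALSE)
    length(unique(m$trace_motif[!has_n])) == 1L && any(!has_n)
  }, logical(1))
  runs[keep, , drop = FALSE]
}

#' Scan a placed cohort for mismatch runs
#'
#' Convenience wrapper: enumerates mismatches for every accepted placement,
#' finds runs, and applies the configured span/motif filters.
#'
#' @param placements accepted placement table from \code{\link{place_traces}}.
#' @param reference a \code{\link{reference_genome}}.
#' @param traces list of \code{\link{trace_read}} keyed by id.
#' @param cfg a \code{\link{scan_config}}.
#' @return list with \code{mismatches} (all mismatches on accepted
#'   placements) and \code{runs} (filtered run table).
#' @export
scan_cohort <- function(placements, reference, traces, cfg = scan_config()) {
  names(traces) <- vapply(traces, function(t) t$trace_id, character(1))
  mms <- vector("list", nrow(placements))
  for (i in seq_len(nrow(placements))) {
    aln <- placements[i, , drop = FALSE]
    mms[[i]] <- enumerate_mismatches(aln, reference, traces[[aln$trace_id]])
  }
  mismatches <- if (length(mms)) do.call(rbind, mms) else empty_mismatch_df()
  runs <- find_runs(mismatches, cfg)
  runs <- apply_span_filter(runs, cfg)
  if (cfg$motif_uniform) runs <- apply_motif_filter(runs, cfg)
  list(mismatches = mismatches, runs = runs)
}

#' Annotate mismatches with the length of the run they belong to
#'
#' @param mismatches mismatch table.
#' @param runs run table built from it (min_run 1 gives every mismatch a
#'   run length).
#' @return the mismatch table with a \code{run_length} column.
#' @export
annotate_run_length <- function(mismatches, runs) {
  mismatches$run_length <- NA_integer_
  if (nrow(runs) == 0L || nrow(mismatches) == 0L) return(mismatches)
  key <- paste(mismatches$trace_id, mismatches$trace_pos)
  for (i in seq_len(nrow(runs))) {
    m <- runs$members[[i]]
    mismatches$run_length[match(paste(m$trace_id, m$trace_pos), key)] <-
      runs$length[[i]]
  }
  mismatches
}
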
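## Detection of the systematic dye sub-peak G-to-A base-calling error: a
## small echo of each peak one position ahead lets the tall A peak of an
## AGA/AGG context swallow the weak G peak, mis-calling it A. The error is
## flagged by its motif signature and by a single-offset alignment of the
## primary against the alternate base calls.

#' Alternate base calls for a trace
#'
#' Base callers can emit, besides the primary call, the second-best base at
#' every position. Under the sub-peak defect the alternate sequence is, to a
#' good approximation, the primary sequence shifted by one position.
#'
#' @param trace_id trace identifier.
#' @param primary_seq primary base calls.
#' @param alternate_seq alternate (second-best) calls, same length.
#' @return list of class \code{alternate_calls}.
#' @export
alternate_calls <- function(trace_id, primary_seq, alternate_seq) {
  primary_seq <- clean_seq(primary_seq)
  alternate_seq <- clean_seq(alternate_seq)
  if (nchar(primary_seq) != nchar(alternate_seq))
    stop("primary and alternate sequences must have equal length",
         call. = FALSE)
  structure(list(trace_id = trace_id, primary_seq = primary_seq,
                 alternate_seq = alternate_seq), class = "alternate_calls")
}

#' Motif flag for the sub-peak artifact
#'
#' TRUE iff the run's type is G>A in read orientation and its uniform
#' reference/trace motif pair is AGA->AAA or AGG->AAG. The test is
#' strand-literal: it inspects read-orientation motifs only, the artifact
#' being a property of the read chemistry, not of the genome.
#'
#' @param run one row of a motif-uniform run table (see
#'   \code{\link{apply_motif_filter}}).
#' @return logical scalar.
#' @export
motif_artifact_flag <- function(run) {
  if (run$type != "G>A") return(FALSE)
  m <- run$members[[1L]]
  ref_m <- unique(m$ref_motif)
  trace_m <- unique(m$trace_motif)
  if (length(ref_m) != 1L || length(trace_m) != 1L) return(FALSE)
  (ref_m == "AGA" && trace_m == "AAA") || (ref_m == "AGG" && trace_m == "AAG")
}

#' Single-offset alternate-call test
#'
#' Aligns the alternate against the primary calls of one trace at offsets
#' -1 and +1 and reports the longest offset-consistent block. Sub-peak
#' artifact traces show a long such block (the alternate is the shifted
#' primary); clean traces show only chance agreement of a few bases.
#'
#' @param calls an \code{\link{alternate_calls}} object.
#' @param min_block minimum block length to flag (default 50: random
#'   400-mers flag far below 1\%, true shifted calls always pass).
#' @return list of class \code{artifact_verdict}: \code{offset_flag},
#'   \code{offset} (-1/+1 or NA), \code{evidence} (longest block length).
#' @export
offset_artifact_test <- function(calls, min_block = 50L) {
  p <- charToRaw(calls$primary_seq)
  a <- charToRaw(calls$alternate_seq)
  L <- length(p)
  if (L < min_block) {
    warning("sequences shorter than min_block; not flagged")
    return(structure(list(offset_flag = FALSE, offset = NA_integer_,
                          evidence = 0L), class = "artifact_verdict"))
  }
  best <- 0L; best_d <- NA_integer_
  for (d in c(-1L, 1L)) {
    ## compare alternate[i] with primary[i + d]
    if (d == 1L) { ai <- 1L:(L - 1L); pi <- 2L:L }
    else { ai <- 2L:L; pi <- 1L:(L - 1L) }
    eq <- a[ai] == p[pi]
    r <- rle(eq)
    longest <- if (any(r$values)) max(r$lengths[r$values]) else 0L
    if (longest > best) { best <- longest; best_d <- d }
  }
  structure(list(offset_flag = best >= min_block,
                 offset = if (best >= min_block) best_d else NA_integer_,
                 evidence = as.integer(best)),
            class = "artifact_verdict")
}

#' @export
print.artifact_verdict <- function(x, ...) {
  cat(sprintf("<artifact_verdict> offset_flag=%s offset=%s evidence=%d\n",
              x$offset_flag, x$offset, x$evidence))
  invisible(x)
}

#' Simulate a sub-peak artifact trace
#'
#' Reads a window of the reference as a trace in which each AGA/AGG site is
#' independently mis-called (G to A) with probability \code{miscall_prob}.
#' Mis-called sites receive low-skewed phred scores in \code{qual_range}
#' (quadratic skew towards the low end — the swallowed G peak is a
#' low-confidence call), always below 40, so artifact traces can never
#' enter the high-quality set. The alternate calls equal the primary calls
#' shifted by +1, the signature of the sub-peak.
#'
#' @param reference_window character scalar (>= 400 bp) to read.
#' @param trace_id identifier for the generated trace.
#' @param miscall_prob per-site mis-call probability.
#' @param qual_range phred range for mis-called sites (low-skewed draw).
#' @param base_qual phred assigned to all other positions.
#' @return list with \code{trace} (a \code{\link{trace_read}}),
#'   \code{calls} (an \code{\link{alternate_calls}}) and \code{sites}
#'   (data frame of mis-called window offsets and quals).
#' @export
simulate_subpeak_trace <- function(reference_window, trace_id = "artifact",
                                   miscall_prob = 0.5,
                                   qual_range = c(2L, 35L),
                                   base_qual = 45L) {
  stopifnot(nchar(reference_window) >= 400L)
  s <- seq_chars(clean_seq(reference_window))
  L <- length(s)
  ## AGA/AGG sites: centre G with A on the left and A or G on the right
  centre <- which(s == "G")
  centre <- centre[centre > 1L & centre < L]
  centre <- centre[s[centre - 1L] == "A" & s[centre + 1L] %in% c("A", "G")]
  hit <- centre[stats::runif(length(centre)) < miscall_prob]
  quals <- rep(as.integer(base_qual), L)
  if (length(hit)) {
    s[hit] <- "A"
    quals[hit] <- qual_range[[1L]] +
      floor(diff(range(qual_range)) * stats::runif(length(hit))^2)
  }
  primary <- paste(s, collapse = "")
  ## sub-peak model: the alternate call at i is the primary call at i+1
  alternate <- paste0(substr(primary, 2L, L),
                      sample(c("A", "C", "G", "T"), 1L))
  list(trace = trace_read(trace_id, primary, quals = quals, origin = "DNA"),
       calls = alternate_calls(trace_id, primary, alternate),
       sites = data.frame(offset = hit - 1L, qual = quals[hit]))
}

#' Trace-level motif flag for the sub-peak artifact
#'
#' A whole G>A run on an artifact trace usually mixes the two signature
#' contexts (AGA->AAA and AGG->AAG), so run-level motif uniformity splits
#' the evidence. This flag splits each G>A run's members by their
#' (reference, trace) motif pair and fires when either signature context
#' accounts for at least \code{min_sites} members of one run.
#'
#' @param runs run table rows belonging to one trace.
#' @param min_sites minimum members sharing one signature context.
#' @return logical scalar.
#' @export
motif_artifact_trace_flag <- function(runs, min_sites = 3L) {
  for (i in seq_len(nrow(runs))) {
    if (runs$type[[i]] != "G>A") next
    m <- runs$members[[i]]
    aga <- sum(m$ref_motif == "AGA" & m$trace_motif == "AAA")
    agg <- sum(m$ref_motif == "AGG" & m$trace_motif == "AAG")
    if (max(aga, agg) >= min_sites) return(TRUE)
  }
  FALSE
}

#' Artifact verdicts for a cohort of runs
#'
#' @param runs motif-uniform run table.
#' @param calls optional named list of \code{\link{alternate_calls}} keyed by
#'   trace id; when present the offset test contributes per-trace flags.
#' @param min_block see \code{\link{offset_artifact_test}}.
#' @return data frame: \code{trace_id}, \code{type}, \code{motif_flag},
#'   \code{offset_flag}, \code{offset}, \code{evidence}.
#' @export
artifact_verdicts <- function(runs, calls = NULL, min_block = 50L) {
  n <- nrow(runs)
  out <- data.frame(trace_id = character(n), type = character(n),
                    motif_flag = logical(n), offset_flag = rep(NA, n),
                    offset = rep(NA_integer_, n),
                    evidence = rep(NA_integer_, n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    out$trace_id[[i]] <- runs$trace_id[[i]]
    out$type[[i]] <- runs$type[[i]]
    out$motif_flag[[i]] <- motif_artifact_flag(runs[i, , drop = FALSE])
    if (!is.null(calls) && runs$trace_id[[i]] %in% names(calls)) {
      v <- offset_artifact_test(calls[[runs$trace_id[[i]]]], min_block)
      out$offset_flag[[i]] <- v$offset_flag
      out$offset[[i]] <- v$offset
      out$evidence[[i]] <- v$evidence
    }
  }
  out
}
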
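## Phred-based editing-enriched (high-quality) and artifact-characterising
## (low-quality) trace sets, and the mismatch spectra derived from runs.

#' Quality-set configuration
#'
#' The high-quality (editing-enriched) set requires, within a run of at
#' least \code{run_min} same-type mismatches of any quality, at least
#' \code{min_qualified} mismatches at phred >= 40 with at least one pair
#' separated by >= 100 bp on the trace. The low-quality (artifact) set
#' mirrors it exactly with the predicate inverted (phred < 10).
#'
#' @param mode \code{"HIGH"} or \code{"LOW"}.
#' @param run_min minimum run length feeding the set.
#' @param q_threshold phred threshold (default 40 for HIGH, 10 for LOW).
#' @param min_qualified minimum number of predicate-passing mismatches.
#' @param min_pair_sep_bp minimum separation of some predicate-passing pair.
#' @return list of class \code{quality_set_config}.
#' @export
quality_set_config <- function(mode = c("HIGH", "LOW"), run_min = 3L,
                               q_threshold = NULL, min_qualified = 2L,
                               min_pair_sep_bp = 100L) {
  mode <- match.arg(mode)
  if (is.null(q_threshold)) q_threshold <- if (mode == "HIGH") 40L else 10L
  stopifnot(min_qualified >= 2L)
  structure(list(mode = mode, run_min = as.integer(run_min),
                 q_threshold = as.integer(q_threshold),
                 min_qualified = as.integer(min_qualified),
                 min_pair_sep_bp = as.integer(min_pair_sep_bp)),
            class = "quality_set_config")
}

qualifies <- function(q, cfg) {
  if (cfg$mode == "HIGH") !is.na(q) & q >= cfg$q_threshold
  else !is.na(q) & q < cfg$q_threshold
}

#' Select quality-enriched traces
#'
#' A trace qualifies if some run of \code{cfg$run_min} or more same-type
#' mismatches (any quality) contains at least \code{cfg$min_qualified}
#' mismatches passing the quality predicate, with at least one passing pair
#' separated by \code{cfg$min_pair_sep_bp} or more on the trace. Only the
#' predicate-passing mismatches are reported. A trace with qualifying runs
#' of several types yields one row per type; duplicate same-type runs count
#' once (the one with the most passing mismatches is reported). Traces
#' without quality scores are excluded with a warning.
#'
#' @param runs run table from \code{\link{find_runs}} built with
#'   \code{min_run == cfg$run_min}.
#' @param cfg a \code{\link{quality_set_config}}.
#' @param traces optional trace list supplying per-trace origin labels.
#' @return data frame of enriched traces: \code{trace_id}, \code{type},
#'   \code{origin}, \code{run_length}, \code{n_reported}, plus list-column
#'   \code{reported} with the passing mismatch rows.
#' @export
select_enriched <- function(runs, cfg = quality_set_config("HIGH"),
                            traces = NULL) {
  origin_of <- function(id) "UNKNOWN"
  if (!is.null(traces)) {
    names(traces) <- vapply(traces, function(t) t$trace_id, character(1))
    origin_of <- function(id)
      if (id %in% names(traces)) traces[[id]]$origin else "UNKNOWN"
  }
  out <- list()
  warned <- character(0)
  for (i in seq_len(nrow(runs))) {
    m <- runs$members[[i]]
    if (all(is.na(m$qual))) {
      warned <- union(warned, runs$trace_id[[i]])
      next
    }
    pass <- m[qualifies(m$qual, cfg), , drop = FALSE]
    if (nrow(pass) < cfg$min_qualified) next
    if (max(pass$trace_pos) - min(pass$trace_pos) < cfg$min_pair_sep_bp) next
    out[[length(out) + 1L]] <- data.frame(
      trace_id = runs$trace_id[[i]], type = runs$type[[i]],
      origin = origin_of(runs$trace_id[[i]]),
      run_length = runs$length[[i]], n_reported = nrow(pass),
      stringsAsFactors = FALSE)
    out[[length(out)]]$reported <- I(list(pass))
  }
  if (length(warned))
    warning("excluded ", length(warned),
            " trace(s) without quality scores: ",
            paste(utils::head(warned, 5), collapse = ", "),
            if (length(warned) > 5) ", ...")
  if (length(out) == 0L) return(empty_enriched_df())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  ## one row per (trace, type): keep the run with the most passing mismatches
  res <- res[order(res$trace_id, res$type, -res$n_reported), , drop = FALSE]
  res <- res[!duplicated(res[c("trace_id", "type")]), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_enriched_df <- function() {
  d <- data.frame(trace_id = character(0), type = character(0),
                  origin = character(0), run_length = integer(0),
                  n_reported = integer(0), stringsAsFactors = FALSE)
  d$reported <- I(list())
  d
}

#' Tally enriched traces by mismatch type
#'
#' Counts traces per substitution type in the presentation used for the
#' per-genome summary tables: the four editing-relevant types (G>A, C>T,
#' A>G, T>C) plus \code{other}, the largest type outside those four.
#' Optionally also reports the RNA-origin subset of each count (the
#' parenthetical values of the summary tables).
#'
#' @param enriched data frame from \code{\link{select_enriched}} (columns
#'   \code{type} and, for the split, \code{origin}).
#' @param by_origin also tally RNA-origin traces.
#' @return data frame with columns \code{type}, \code{count} and (when
#'   \code{by_origin}) \code{rna_count}; rows G>A, C>T, A>G, T>C, other.
#' @export
tally_by_type <- function(enriched, by_origin = FALSE) {
  cnt <- function(df) {
    tab <- table(factor(df$type, levels = MISMATCH_TYPES))
    other_types <- setdiff(MISMATCH_TYPES, EDITING_TYPES)
    c(as.integer(tab[EDITING_TYPES]),
      if (length(other_types)) max(as.integer(tab[other_types])) else 0L)
  }
  out <- data.frame(type = c(EDITING_TYPES, "other"),
                    count = cnt(enriched), stringsAsFactors = FALSE)
  if (by_origin)
    out$rna_count <- cnt(enriched[enriched$origin == "RNA", , drop = FALSE])
  out
}

#' Run-type spectrum by minimum run length
#'
#' For each k = 1..max_k, the percent frequency of each substitution type
#' among runs of length >= k. Each k-slice sums to 100 (over types present).
#'
#' @param runs run table from \code{\link{find_runs}} (unfiltered by type).
#' @param max_k largest minimum-length threshold.
#' @return numeric matrix, 12 types x max_k, percent per column.
#' @export
spectrum_by_run_length <- function(runs, max_k = 10L) {
  out <- matrix(NA_real_, nrow = length(MISMATCH_TYPES), ncol = max_k,
                dimnames = list(MISMATCH_TYPES, paste0("k", seq_len(max_k))))
  for (k in seq_len(max_k)) {
    sub <- runs[runs$length >= k, , drop = FALSE]
    if (nrow(sub) == 0L) next
    tab <- table(factor(sub$type, levels = MISMATCH_TYPES))
    out[, k] <- 100 * as.numeric(tab) / sum(tab)
  }
  out
}

#' Mismatch-type spectrum by phred quality bin
#'
#' Pools the member mismatches of the supplied runs and, within each phred
#' bin (closed on the left, open on the right), reports the percent share of
#' each substitution type.
#'
#' @param runs run table from \code{\link{find_runs}}; member quals must be
#'   present (NA-qual mismatches are ignored).
#' @param bins numeric vector of bin edges, e.g. \code{c(0,10,20,30,40,94)};
#'   a value q lands in bin i when \code{bins[i] <= q < bins[i+1]}.
#' @return numeric matrix, 12 types x (length(bins)-1), percent per column;
#'   columns with no mismatches are NA.
#' @export
spectrum_by_quality <- function(runs, bins = c(0, 10, 20, 30, 40, 94)) {
  mm <- if (nrow(runs)) do.call(rbind, runs$members) else empty_mismatch_df()
  mm <- mm[!is.na(mm$qual), , drop = FALSE]
  nb <- length(bins) - 1L
  lab <- paste0("[", bins[-length(bins)], ",", bins[-1], ")")
  out <- matrix(NA_real_, nrow = length(MISMATCH_TYPES), ncol = nb,
                dimnames = list(MISMATCH_TYPES, lab))
  if (nrow(mm) == 0L) return(out)
  bin <- findInterval(mm$qual, bins, rightmost.closed = FALSE,
                      left.open = FALSE)
  for (i in seq_len(nb)) {
    sub <- mm$type[bin == i]
    if (length(sub) == 0L) next
    tab <- table(factor(sub, levels = MISMATCH_TYPES))
    out[, i] <- 100 * as.numeric(tab) / sum(tab)
  }
  out
}
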
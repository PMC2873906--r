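## Orchestration: chain simulate -> place -> scan -> enrich -> artifact with
## a machine-readable manifest (per-stage record counts, checksums, seed).
## A thin Rscript front-end over this lives in inst/cli/editscan.

#' Default pipeline configuration
#'
#' Stage parameters default to the strict survey values: placement 400 bp /
#' 97\% identity / 60 bp seed; runs of 5 with uniform motif for the survey
#' mode, runs of 3 with the phred-40 predicate for the enrichment mode;
#' span 100 bp.
#'
#' @param mode \code{"enrich"} (runs of 3 + quality sets) or
#'   \code{"survey"} (runs of 5 + motif uniformity).
#' @param sim a \code{\link{sim_config}} (used when no external inputs are
#'   given).
#' @param place a \code{\link{filter_config}}.
#' @param scan a \code{\link{scan_config}}; defaults depend on \code{mode}.
#' @param quality a \code{\link{quality_set_config}}.
#' @param min_block offset-test block threshold.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(mode = c("enrich", "survey"),
                            sim = sim_config(),
                            place = filter_config(),
                            scan = NULL,
                            quality = quality_set_config("HIGH"),
                            min_block = 50L) {
  mode <- match.arg(mode)
  if (is.null(scan))
    scan <- if (mode == "survey")
      scan_config(min_run = 5L, min_span_bp = 100L, motif_uniform = TRUE)
    else
      scan_config(min_run = 3L, min_span_bp = 0L, motif_uniform = FALSE)
  structure(list(mode = mode, sim = sim, place = place, scan = scan,
                 quality = quality, min_block = min_block),
            class = "pipeline_config")
}

#' Run the full scanning pipeline
#'
#' Simulates (or accepts) a cohort, places every trace under the strict
#' criteria, scans accepted placements for same-type mismatch runs, builds
#' the configured quality set, flags artifact candidates, and returns all
#' stage outputs with a manifest of per-stage record counts. Counts are
#' non-increasing along placement -> scan -> enrichment for a fixed type.
#' Deterministic given the configuration.
#'
#' @param cfg a \code{\link{pipeline_config}}.
#' @param cohort optional pre-built cohort (result of
#'   \code{\link{simulate_cohort}} or a list with \code{reference},
#'   \code{traces}, optionally \code{calls}); when absent one is simulated
#'   from \code{cfg$sim}.
#' @param out_dir optional directory; when given, stage outputs are written
#'   (cohort files, placements.tsv, runs.tsv, enriched.tsv, mismatch BED,
#'   manifest.json).
#' @return list of class \code{pipeline_result}: \code{cohort},
#'   \code{placements}, \code{placement_summary}, \code{mismatches},
#'   \code{runs}, \code{enriched}, \code{verdicts}, \code{manifest}.
#' @export
run_pipeline <- function(cfg = pipeline_config(), cohort = NULL,
                         out_dir = NULL) {
  if (is.null(cohort)) cohort <- simulate_cohort(cfg$sim)
  traces <- cohort$traces
  reference <- cohort$reference

  placed <- place_traces(traces, reference, cfg$place)
  scan <- scan_cohort(placed$placements, reference, traces, cfg$scan)
  enriched <- if (cfg$mode == "enrich")
    select_enriched(scan$runs, cfg$quality, traces = traces)
  else empty_enriched_df()
  motif_runs <- apply_motif_filter(scan$runs, cfg$scan)
  verdicts <- artifact_verdicts(motif_runs, calls = cohort$calls,
                                min_block = cfg$min_block)

  manifest <- list(
    tool = "editscan",
    version = as.character(utils::packageVersion("editscan")),
    mode = cfg$mode,
    seed = if (!is.null(cfg$sim)) cfg$sim$seed else NA,
    counts = list(
      traces_in = length(traces),
      unique = unname(placed$summary[["UNIQUE"]]),
      multiple = unname(placed$summary[["MULTIPLE"]]),
      none = unname(placed$summary[["NONE"]]),
      traces_with_runs = length(unique(scan$runs$trace_id)),
      runs = nrow(scan$runs),
      enriched_traces = length(unique(enriched$trace_id)),
      artifact_flagged = sum(verdicts$motif_flag)
    ),
    params = list(
      min_aln_len = cfg$place$min_aln_len,
      min_identity = cfg$place$min_identity,
      seed_len = cfg$place$seed_len,
      min_run = cfg$scan$min_run,
      min_span_bp = cfg$scan$min_span_bp,
      q_threshold = cfg$quality$q_threshold,
      quality_mode = cfg$quality$mode
    )
  )

  res <- structure(
    list(cohort = cohort, placements = placed$placements,
         placement_summary = placed$summary, mismatches = scan$mismatches,
         runs = scan$runs, enriched = enriched, verdicts = verdicts,
         manifest = manifest),
    class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_outputs(res, cfg, out_dir)
  res
}

write_pipeline_outputs <- function(res, cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(res$cohort$truth)) write_cohort(res$cohort, out_dir)
  utils::write.table(res$placements, file.path(out_dir, "placements.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  runs_flat <- res$runs[setdiff(names(res$runs), "members")]
  utils::write.table(runs_flat, file.path(out_dir, "runs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  enr_flat <- res$enriched[setdiff(names(res$enriched), "reported")]
  utils::write.table(enr_flat, file.path(out_dir, "enriched.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$verdicts, file.path(out_dir, "artifact.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  mm <- annotate_run_length(res$mismatches, res$runs)
  mm <- mm[!is.na(mm$run_length), , drop = FALSE]
  write_bed(bed_rows(mm, res$cohort$traces),
            file.path(out_dir, "mismatches.bed"))
  manifest <- res$manifest
  manifest$checksums <- input_checksums(out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

input_checksums <- function(dir) {
  files <- c("reference.fa", "traces.fa", "traces.qual")
  files <- files[file.exists(file.path(dir, files))]
  sums <- tools::md5sum(file.path(dir, files))
  names(sums) <- files
  as.list(sums)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cts <- x$manifest$counts
  cat("<pipeline_result>\n")
  cat(sprintf("  traces: %d in; %d UNIQUE / %d MULTIPLE / %d NONE\n",
              cts$traces_in, cts$unique, cts$multiple, cts$none))
  cat(sprintf("  runs: %d (on %d traces); enriched traces: %d; artifact-flagged runs: %d\n",
              cts$runs, cts$traces_with_runs, cts$enriched_traces,
              cts$artifact_flagged))
  invisible(x)
}

#' Read a pipeline configuration from a YAML file
#'
#' One section per stage (\code{sim}, \code{place}, \code{scan},
#' \code{quality}) plus top-level \code{mode}; absent keys keep defaults.
#'
#' @param path YAML file.
#' @param overrides named list applied on top of the file values
#'   (CLI flags).
#' @return a \code{\link{pipeline_config}}.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  raw <- if (!is.null(path)) yaml::read_yaml(path) else list()
  raw <- utils::modifyList(raw, overrides)
  sim_args <- raw$sim %||% list()
  pipeline_config(
    mode = raw$mode %||% "enrich",
    sim = do.call(sim_config, sim_args),
    place = do.call(filter_config, raw$place %||% list()),
    scan = if (!is.null(raw$scan)) do.call(scan_config, raw$scan) else NULL,
    quality = do.call(quality_set_config, raw$quality %||% list()),
    min_block = raw$min_block %||% 50L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
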
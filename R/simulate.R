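## Seeded generator of reference + trace cohorts: capillary-length reads with
## phred-calibrated background error, planted A-to-I editing clusters (with
## ADAR upstream-G avoidance), APOBEC-style G-to-A clusters in repeat
## overlapping DNA traces, and dye sub-peak artifact traces, with full truth
## tables.

#' Simulation configuration
#'
#' Defaults encode the cohort conditions used throughout the package's
#' tests: capillary read lengths (400-900 bp), a flat high-quality profile
#' with a degraded tail, editing clusters of high-phred A>G sites spanning
#' well over 100 bp, low-quality AGA/AGG mis-calls for artifact traces, and
#' a background of true sequence variants that supplies the symmetric
#' high-quality mismatch spectrum.
#'
#' @param seed integer seed; the generator is fully deterministic given the
#'   configuration.
#' @param ref_len reference length in bp (single chromosome).
#' @param n_repeat_copies,repeat_len,repeat_divergence planted near-identical
#'   repeat family (Alu/IAP stand-in).
#' @param n_traces cohort size.
#' @param trace_len_range sampled read length range, bp.
#' @param qual_high flat phred of the read body.
#' @param qual_tail_start fraction of the read after which quality degrades
#'   linearly.
#' @param qual_tail_end phred at the final base.
#' @param mutation_rate per-bp probability that the sequenced individual
#'   truly differs from the reference (uniform over the three alternatives;
#'   these mismatches carry the position's phred).
#' @param rna_fraction fraction of non-artifact traces of RNA origin.
#' @param editing list: \code{fraction} of RNA traces edited,
#'   \code{sites_per_cluster} (>= 3), \code{cluster_window} bp,
#'   \code{min_span_bp}, \code{qual_range} (phred 40-50),
#'   \code{upstream_g_weight} (non-G 5' neighbours preferred that-to-1).
#' @param dna_editing list: \code{fraction} of repeat-overlapping DNA traces
#'   edited, \code{sites_per_cluster}, \code{min_span_bp},
#'   \code{qual_range}, \code{gg_weight}/\code{ga_weight} (5' G and A
#'   dinucleotide preference).
#' @param artifact list: \code{fraction} of traces, \code{miscall_prob} per
#'   AGA/AGG site, \code{qual_range} (low-skewed, always < 40).
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       ref_len = 50000L,
                       n_repeat_copies = 6L, repeat_len = 300L,
                       repeat_divergence = 0.01,
                       n_traces = 500L,
                       trace_len_range = c(400L, 900L),
                       qual_high = 45L, qual_tail_start = 0.8,
                       qual_tail_end = 25L,
                       mutation_rate = 1e-3,
                       rna_fraction = 0.4,
                       editing = list(),
                       dna_editing = list(),
                       artifact = list()) {
  editing <- utils::modifyList(list(
    fraction = 0.5, sites_per_cluster = 6L, cluster_window = 350L,
    min_span_bp = 200L, qual_range = c(40L, 50L), upstream_g_weight = 4
  ), editing)
  dna_editing <- utils::modifyList(list(
    fraction = 0.3, sites_per_cluster = 5L, min_span_bp = 150L,
    qual_range = c(40L, 50L), gg_weight = 8, ga_weight = 3
  ), dna_editing)
  artifact <- utils::modifyList(list(
    fraction = 0.15, miscall_prob = 0.6, qual_range = c(2L, 35L)
  ), artifact)
  stopifnot(ref_len >= 10L * repeat_len || n_repeat_copies == 0L,
            editing$fraction >= 0, editing$fraction <= 1,
            dna_editing$fraction >= 0, dna_editing$fraction <= 1,
            artifact$fraction >= 0, artifact$fraction <= 1,
            rna_fraction >= 0, rna_fraction <= 1,
            editing$sites_per_cluster >= 3L)
  if (editing$min_span_bp >= trace_len_range[[1L]])
    stop("editing cluster span exceeds the shortest trace", call. = FALSE)
  structure(list(seed = as.integer(seed), ref_len = as.integer(ref_len),
                 n_repeat_copies = as.integer(n_repeat_copies),
                 repeat_len = as.integer(repeat_len),
                 repeat_divergence = repeat_divergence,
                 n_traces = as.integer(n_traces),
                 trace_len_range = as.integer(trace_len_range),
                 qual_high = as.integer(qual_high),
                 qual_tail_start = qual_tail_start,
                 qual_tail_end = as.integer(qual_tail_end),
                 mutation_rate = mutation_rate,
                 rna_fraction = rna_fraction,
                 editing = editing, dna_editing = dna_editing,
                 artifact = artifact),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

#' Simulate a reference genome with a planted repeat family
#'
#' An i.i.d. uniform ACGT background of \code{ref_len} bp carrying
#' \code{n_repeat_copies} non-overlapping copies of one random
#' \code{repeat_len}-mer, each copy independently diverged by
#' \code{repeat_divergence} substitutions per bp. Deterministic given the
#' configuration (seeded internally from \code{cfg$seed}).
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list: \code{reference} (a \code{\link{reference_genome}}, one
#'   chromosome \code{chr1}), \code{repeats} (GRanges of the planted
#'   copies), \code{repeat_df} (chrom/start/end data frame, 0-based
#'   half-open).
#' @export
make_reference <- function(cfg) {
  set.seed(cfg$seed)
  s <- sample(BASES, cfg$ref_len, replace = TRUE)
  starts <- integer(0)
  if (cfg$n_repeat_copies > 0L) {
    motif <- sample(BASES, cfg$repeat_len, replace = TRUE)
    while (length(starts) < cfg$n_repeat_copies) {
      cand <- sample.int(cfg$ref_len - cfg$repeat_len, 1L) - 1L  # 0-based
      if (all(abs(cand - starts) >= cfg$repeat_len) || !length(starts)) {
        copy <- motif
        ndiv <- stats::rbinom(1L, cfg$repeat_len, cfg$repeat_divergence)
        if (ndiv > 0L) {
          at <- sample.int(cfg$repeat_len, ndiv)
          copy[at] <- vapply(copy[at], function(b)
            sample(setdiff(BASES, b), 1L), character(1))
        }
        s[(cand + 1L):(cand + cfg$repeat_len)] <- copy
        starts <- c(starts, cand)
      }
    }
  }
  repeat_df <- data.frame(chrom = rep("chr1", length(starts)),
                          start = starts, end = starts + cfg$repeat_len,
                          stringsAsFactors = FALSE)
  repeat_df <- repeat_df[order(repeat_df$start), , drop = FALSE]
  repeats <- if (nrow(repeat_df))
    interval_set(repeat_df$chrom, repeat_df$start, repeat_df$end,
                 label = "simrep")
  else GenomicRanges::GRanges()
  list(reference = reference_genome(c(chr1 = paste(s, collapse = ""))),
       repeats = repeats, repeat_df = repeat_df)
}

## phred profile along a read: flat body, linear decay over the tail
qual_profile <- function(cfg, len) {
  q <- rep(cfg$qual_high, len)
  t0 <- floor(cfg$qual_tail_start * len) + 1L
  if (t0 <= len && cfg$qual_tail_end < cfg$qual_high) {
    frac <- seq(t0, len) - t0
    q[t0:len] <- round(cfg$qual_high -
      (cfg$qual_high - cfg$qual_tail_end) * frac / max(1L, len - t0))
  }
  as.integer(q)
}

## weighted sample of `k` distinct positions with span >= min_span; NULL if
## infeasible after `tries` attempts
sample_cluster <- function(cand, weights, k, min_span, tries = 30L) {
  if (length(cand) < k) return(NULL)
  for (i in seq_len(tries)) {
    pick <- sort(sample(cand, k, prob = weights))
    if (pick[[k]] - pick[[1L]] >= min_span) return(pick)
  }
  NULL
}

#' Simulate a trace cohort with truth tables
#'
#' Each trace samples a uniform position, strand and length on the
#' reference; true variants and phred-calibrated base errors (error
#' probability \code{10^(-q/10)}) are applied; editing clusters are planted
#' in RNA traces (A>G in transcript sense, high phred, upstream-G
#' avoidance), APOBEC-style G>A clusters in repeat-overlapping DNA traces
#' (GG/GA dinucleotide preference), and artifact traces are produced by
#' \code{\link{simulate_subpeak_trace}}. Deterministic given the
#' configuration (seeded internally from \code{cfg$seed + 1}).
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param ref_obj result of \code{\link{make_reference}}.
#' @return list: \code{traces} (list of \code{\link{trace_read}}),
#'   \code{truth} (list of \code{traces} and \code{sites} data frames),
#'   \code{calls} (named list of \code{\link{alternate_calls}} for artifact
#'   traces).
#' @export
make_traces <- function(cfg, ref_obj) {
  set.seed(cfg$seed + 1L)
  reference <- ref_obj$reference
  chromseq <- unclass(reference)[["chr1"]]
  L <- nchar(chromseq)
  rpt <- ref_obj$repeat_df
  traces <- vector("list", cfg$n_traces)
  calls <- list()
  lab_rows <- vector("list", cfg$n_traces)
  site_rows <- list()
  centers <- c("WUGSC", "BROAD", "BCM", "JGI")
  for (i in seq_len(cfg$n_traces)) {
    id <- sprintf("t%05d", i)
    len <- sample(seq(cfg$trace_len_range[[1L]], cfg$trace_len_range[[2L]]),
                  1L)
    start <- sample.int(L - len + 1L, 1L) - 1L  # 0-based
    strand <- sample(c("+", "-"), 1L)
    center <- sample(centers, 1L)
    in_repeat <- nrow(rpt) > 0L &&
      any(pmin(rpt$end, start + len) - pmax(rpt$start, start) > 0L)

    if (stats::runif(1L) < cfg$artifact$fraction) {
      ## artifact trace: plus-strand read of the window, sub-peak mis-calls
      sp <- simulate_subpeak_trace(
        substr(chromseq, start + 1L, start + len), trace_id = id,
        miscall_prob = cfg$artifact$miscall_prob,
        qual_range = cfg$artifact$qual_range,
        base_qual = cfg$qual_high)
      t <- sp$trace
      t$center <- center; t$organism <- "simulated"
      traces[[i]] <- t
      calls[[id]] <- sp$calls
      lab_rows[[i]] <- data.frame(
        trace_id = id, label = "artifact", origin = "DNA", chrom = "chr1",
        start = start, end = start + len, strand = "+",
        stringsAsFactors = FALSE)
      if (nrow(sp$sites))
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          trace_id = id, trace_pos = sp$sites$offset,
          ref_pos = start + sp$sites$offset, type = "G>A",
          qual = sp$sites$qual, planted = "artifact",
          stringsAsFactors = FALSE)
      next
    }

    origin <- if (stats::runif(1L) < cfg$rna_fraction) "RNA" else "DNA"
    edited_rna <- origin == "RNA" && stats::runif(1L) < cfg$editing$fraction
    edited_dna <- origin == "DNA" && in_repeat &&
      stats::runif(1L) < cfg$dna_editing$fraction

    w <- seq_chars(substr(chromseq, start + 1L, start + len))
    ## true variants of the sequenced individual
    vidx <- which(stats::runif(len) < cfg$mutation_rate)
    for (j in vidx) w[[j]] <- sample(setdiff(BASES, w[[j]]), 1L)

    planted <- NULL
    if (edited_rna) {
      planted <- plant_editing_cluster(w, cfg$editing)
      edited_rna <- !is.null(planted)
    }
    if (edited_dna) {
      planted <- plant_dna_editing_cluster(w, cfg$dna_editing)
      edited_dna <- !is.null(planted)
    }
    if (!is.null(planted)) w <- planted$w

    read <- if (strand == "+") paste(w, collapse = "")
            else revcomp(paste(w, collapse = ""))
    quals <- qual_profile(cfg, len)
    protected <- integer(0)
    if (!is.null(planted)) {
      ## window offset -> read position
      rp <- if (strand == "+") planted$sites
            else len - 1L - planted$sites
      quals[rp + 1L] <- sample(
        seq(planted$qual_range[[1L]], planted$qual_range[[2L]]),
        length(rp), replace = TRUE)
      protected <- rp
      read_type <- if (planted$sense == strand) planted$sense_type
                   else complement_type(planted$sense_type)
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        trace_id = id, trace_pos = rp, ref_pos = start + planted$sites,
        type = read_type, qual = quals[rp + 1L],
        planted = if (edited_rna) "edited_rna" else "edited_dna",
        stringsAsFactors = FALSE)
    }
    ## phred-calibrated background base errors
    rc <- seq_chars(read)
    errp <- 10^(-quals / 10)
    eidx <- setdiff(which(stats::runif(len) < errp), protected + 1L)
    for (j in eidx) rc[[j]] <- sample(setdiff(BASES, rc[[j]]), 1L)
    traces[[i]] <- trace_read(id, paste(rc, collapse = ""), quals = quals,
                              origin = origin, center = center,
                              organism = "simulated")
    lab_rows[[i]] <- data.frame(
      trace_id = id,
      label = if (edited_rna) "edited_rna"
              else if (edited_dna) "edited_dna" else "clean",
      origin = origin, chrom = "chr1", start = start, end = start + len,
      strand = strand, stringsAsFactors = FALSE)
  }
  truth_traces <- do.call(rbind, lab_rows)
  truth_sites <- if (length(site_rows)) do.call(rbind, site_rows)
    else data.frame(trace_id = character(0), trace_pos = integer(0),
                    ref_pos = integer(0), type = character(0),
                    qual = integer(0), planted = character(0),
                    stringsAsFactors = FALSE)
  rownames(truth_traces) <- rownames(truth_sites) <- NULL
  list(traces = traces,
       truth = list(traces = truth_traces, sites = truth_sites),
       calls = calls)
}

## flip an editing pair to its complement (read on the other strand)
complement_type <- function(type) {
  c("A>G" = "T>C", "T>C" = "A>G", "G>A" = "C>T", "C>T" = "G>A")[[type]]
}

## ADAR cluster: A>G in transcript sense, 5' sense neighbour non-G preferred
## upstream_g_weight : 1. Operates on the genomic-plus window `w`; returns
## the edited window, 0-based window offsets of the sites, the transcript
## sense strand and the sense-orientation type.
plant_editing_cluster <- function(w, ecfg) {
  len <- length(w)
  sense <- sample(c("+", "-"), 1L)
  j <- 2:(len - 1L)                    # keep full neighbours
  if (sense == "+") {
    cand <- j[w[j] == "A"]
    up <- w[cand - 1L]
  } else {
    cand <- j[w[j] == "T"]
    up <- comp_chars(w[cand + 1L])
  }
  cw <- min(ecfg$cluster_window, len)
  off <- sample.int(len - cw + 1L, 1L) - 1L
  inwin <- cand > off & cand <= off + cw
  cand <- cand[inwin]; up <- up[inwin]
  weights <- ifelse(up == "G", 1, ecfg$upstream_g_weight)
  pick <- sample_cluster(cand, weights, ecfg$sites_per_cluster,
                         ecfg$min_span_bp)
  if (is.null(pick)) return(NULL)
  w[pick] <- if (sense == "+") "G" else "C"
  list(w = w, sites = pick - 1L, sense = sense, sense_type = "A>G",
       qual_range = ecfg$qual_range)
}

## APOBEC cluster: G>A in cDNA sense with GG/GA 5' dinucleotide preference.
plant_dna_editing_cluster <- function(w, dcfg) {
  len <- length(w)
  sense <- sample(c("+", "-"), 1L)
  j <- 2:(len - 1L)
  if (sense == "+") {
    cand <- j[w[j] == "G"]
    up <- w[cand - 1L]
  } else {
    cand <- j[w[j] == "C"]
    up <- comp_chars(w[cand + 1L])
  }
  weights <- ifelse(up == "G", dcfg$gg_weight,
                    ifelse(up == "A", dcfg$ga_weight, 1))
  pick <- sample_cluster(cand, weights, dcfg$sites_per_cluster,
                         dcfg$min_span_bp)
  if (is.null(pick)) return(NULL)
  w[pick] <- if (sense == "+") "A" else "T"
  list(w = w, sites = pick - 1L, sense = sense, sense_type = "G>A",
       qual_range = dcfg$qual_range)
}

#' Simulate a full cohort
#'
#' \code{\link{make_reference}} + \code{\link{make_traces}} under one
#' configuration.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list: \code{cfg}, \code{reference}, \code{repeats},
#'   \code{repeat_df}, \code{traces}, \code{truth}, \code{calls}.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  ref_obj <- make_reference(cfg)
  tr <- make_traces(cfg, ref_obj)
  c(list(cfg = cfg), ref_obj, tr)
}

#' Write a simulated cohort to disk
#'
#' Emits \code{reference.fa}, \code{traces.fa}, \code{traces.qual},
#' \code{meta.tsv}, \code{truth_traces.tsv}, \code{truth_sites.tsv} and
#' \code{repeats.bed} into a directory.
#'
#' @param sim result of \code{\link{simulate_cohort}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$reference, file.path(dir, "reference.fa"))
  write_fasta(sim$traces, file.path(dir, "traces.fa"))
  write_qual(sim$traces, file.path(dir, "traces.qual"))
  meta <- data.frame(
    trace_id = vapply(sim$traces, function(t) t$trace_id, character(1)),
    center = vapply(sim$traces, function(t) t$center, character(1)),
    organism = vapply(sim$traces, function(t) t$organism, character(1)),
    origin = vapply(sim$traces, function(t) t$origin, character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(meta, file.path(dir, "meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$traces, file.path(dir, "truth_traces.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$sites, file.path(dir, "truth_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(sim$repeat_df))
    utils::write.table(sim$repeat_df, file.path(dir, "repeats.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  invisible(dir)
}
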
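## Strict trace placement: a minimal seed-and-extend ungapped aligner for
## synthetic cohorts, plus the acceptance filter (>=400 bp, >=97% identity,
## no indels, unique locus) applied to internal or externally supplied
## candidate placements.

#' Placement filter configuration
#'
#' Defaults encode the strict acceptance criteria: alignments of at least
#' 400 bp at 97\% identity, no insertions or deletions, and a unique locus.
#'
#' @param min_aln_len minimum alignment length in bp.
#' @param min_identity minimum fraction identity over the aligned window.
#' @param seed_len exact-match seed length for the internal aligner.
#' @param require_unique discard traces placing at more than one locus.
#' @return list of class \code{filter_config}.
#' @export
filter_config <- function(min_aln_len = 400L, min_identity = 0.97,
                          seed_len = 60L, require_unique = TRUE) {
  stopifnot(min_identity > 0, min_identity <= 1,
            seed_len <= min_aln_len, seed_len >= 8L)
  structure(list(min_aln_len = as.integer(min_aln_len),
                 min_identity = min_identity,
                 seed_len = as.integer(seed_len),
                 allow_indels = FALSE,
                 require_unique = isTRUE(require_unique)),
            class = "filter_config")
}

#' Build an exact seed index over a reference
#'
#' Hashes every \code{seed_len}-mer of every reference sequence to its
#' positions. Seeds containing \code{N} are skipped. Reverse-complement
#' lookup happens at query time (the query is reverse-complemented, not the
#' index).
#'
#' @param reference a \code{\link{reference_genome}}.
#' @param seed_len seed length (>= 8).
#' @return list of class \code{seed_index} with the hash environment,
#'   \code{seed_len} and chromosome names.
#' @export
build_seed_index <- function(reference, seed_len = 60L) {
  seed_len <- as.integer(seed_len)
  stopifnot(seed_len >= 8L)
  env <- new.env(hash = TRUE, parent = emptyenv())
  chroms <- names(unclass(reference))
  all_kmers <- character(0)
  all_chrom <- integer(0)
  all_pos <- integer(0)
  for (ci in seq_along(chroms)) {
    s <- unclass(reference)[[ci]]
    L <- nchar(s)
    if (L < seed_len) next
    starts <- seq_len(L - seed_len + 1L)  # 1-based
    kmers <- substring(s, starts, starts + seed_len - 1L)
    keep <- !grepl("N", kmers, fixed = TRUE)
    all_kmers <- c(all_kmers, kmers[keep])
    all_chrom <- c(all_chrom, rep.int(ci, sum(keep)))
    all_pos <- c(all_pos, starts[keep] - 1L)  # 0-based
  }
  if (length(all_kmers) == 0L)
    warning("reference shorter than seed length; empty index")
  ## each hit is packed into one double (chrom * 2^32 + pos, both exact)
  code <- all_chrom * 2^32 + all_pos
  list2env(split(code, all_kmers), envir = env)
  structure(list(env = env, seed_len = seed_len, chroms = chroms),
            class = "seed_index")
}

#' Look up a seed in the index
#'
#' @param index a \code{\link{build_seed_index}} result.
#' @param kmer seed string of length \code{index$seed_len}.
#' @return integer matrix with columns \code{chrom} (index into
#'   \code{index$chroms}) and \code{pos} (0-based), zero rows if absent.
#' @export
seed_hits <- function(index, kmer) {
  code <- if (exists(kmer, envir = index$env, inherits = FALSE))
    get(kmer, envir = index$env) else numeric(0)
  decode_hits(code)
}

decode_hits <- function(code) {
  chrom <- floor(code / 2^32)
  cbind(chrom = as.integer(chrom), pos = as.integer(code - chrom * 2^32))
}

#' Align one trace with seed-and-extend (ungapped)
#'
#' Every seed of the trace (both strands) is looked up in the index; each hit
#' defines a diagonal, on which the alignment is extended in both directions
#' to the maximal window bounded by sequence ends or by an \code{N} in either
#' sequence. Candidates are deduplicated by (chrom, strand, diagonal) and by
#' identical windows, and report length, identity and mismatch count over
#' every aligned column. No candidate contains an indel by construction.
#'
#' @param trace a \code{\link{trace_read}}.
#' @param index a \code{\link{seed_index}} built with \code{cfg$seed_len}.
#' @param reference the \code{\link{reference_genome}} behind the index.
#' @param cfg a \code{\link{filter_config}}.
#' @return data frame of candidate placements (possibly empty) with columns
#'   \code{trace_id}, \code{chrom}, \code{ref_start}, \code{ref_end},
#'   \code{trace_start}, \code{trace_end}, \code{strand}, \code{length},
#'   \code{n_mismatch}, \code{identity}, \code{gapped}.
#' @export
align_trace <- function(trace, index, reference, cfg = filter_config()) {
  k <- index$seed_len
  read <- trace$sequence
  L <- nchar(read)
  out <- list()
  if (L >= k) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") read else revcomp(read)
      sraw <- charToRaw(s)
      offs <- seq_len(L - k + 1L) - 1L  # 0-based query offsets
      kmers <- substring(s, offs + 1L, offs + k)
      hits <- mget(kmers, envir = index$env, ifnotfound = list(NULL))
      nhit <- lengths(hits)
      if (!any(nhit > 0L)) next
      hm <- decode_hits(unlist(hits[nhit > 0L], use.names = FALSE))
      off_all <- rep.int(offs[nhit > 0L], nhit[nhit > 0L])
      diag_all <- hm[, "pos"] - off_all
      ## one extension per (chrom, diagonal); keep the first seed offset
      first <- !duplicated(cbind(hm[, "chrom"], diag_all))
      for (h in which(first)) {
        ci <- hm[h, "chrom"]
        diag <- diag_all[[h]]
        cand <- extend_on_diagonal(sraw, unclass(reference)[[ci]],
                                   diag, off_all[[h]], k)
        if (is.null(cand)) next
        ## map s-coordinates back to read orientation for minus strand
        if (strand == "+") {
          ts <- cand$q0; te <- cand$q1
        } else {
          ts <- L - cand$q1; te <- L - cand$q0
        }
        out[[length(out) + 1L]] <- data.frame(
          trace_id = trace$trace_id,
          chrom = index$chroms[[ci]],
          ref_start = diag + cand$q0, ref_end = diag + cand$q1,
          trace_start = ts, trace_end = te,
          strand = strand,
          length = cand$q1 - cand$q0,
          n_mismatch = cand$mm,
          identity = 1 - cand$mm / (cand$q1 - cand$q0),
          gapped = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(empty_placement_df())
  res <- do.call(rbind, out)
  ## identical windows can arise from different diagonals after N-trimming
  res[!duplicated(res[c("chrom", "strand", "ref_start", "ref_end",
                        "trace_start", "trace_end")]), , drop = FALSE]
}

## Extend the diagonal through query offset q_seed (0-based) to the maximal
## N-free window. sraw: raw query (strand-adjusted); refseq: chromosome
## string; diag: ref_pos - query_offset. Returns q0/q1 (query window,
## half-open) and mismatch count, or NULL if the seed region is invalid.
extend_on_diagonal <- function(sraw, refseq, diag, q_seed, k) {
  Lq <- length(sraw)
  Lr <- nchar(refseq)
  q0 <- max(0L, -diag)
  q1 <- min(Lq, Lr - diag)
  if (q1 <= q0) return(NULL)
  rraw <- charToRaw(substr(refseq, diag + q0 + 1L, diag + q1))
  qraw <- sraw[(q0 + 1L):q1]
  nN <- charToRaw("N")
  bad <- which(qraw == nN | rraw == nN)
  ## restrict to the N-free stretch containing the seed
  rel_seed <- q_seed - q0 + 1L
  lo <- 1L; hi <- length(qraw)
  if (length(bad)) {
    below <- bad[bad < rel_seed]
    above <- bad[bad >= rel_seed]
    if (length(below)) lo <- max(below) + 1L
    if (length(above)) hi <- min(above) - 1L
    if (hi < lo) return(NULL)
  }
  mm <- sum(qraw[lo:hi] != rraw[lo:hi])
  list(q0 = q0 + lo - 1L, q1 = q0 + hi, mm = as.integer(mm))
}

empty_placement_df <- function() {
  data.frame(trace_id = character(0), chrom = character(0),
             ref_start = integer(0), ref_end = integer(0),
             trace_start = integer(0), trace_end = integer(0),
             strand = character(0), length = integer(0),
             n_mismatch = integer(0), identity = numeric(0),
             gapped = logical(0), stringsAsFactors = FALSE)
}

#' Classify candidate placements of one trace
#'
#' Candidates failing the length/identity thresholds or containing indels are
#' dropped; the survivors are grouped into loci (same chromosome and strand,
#' reference intervals overlapping by at least 50\% reciprocally — seed hits
#' tiling one placement must not fake multiplicity). Zero passing loci gives
#' \code{NONE}, one gives \code{UNIQUE} (with the best record), two or more
#' give \code{MULTIPLE} and the trace is discarded downstream.
#'
#' @param candidates data frame from \code{\link{align_trace}} or
#'   \code{\link{read_alignment_table}} (one trace).
#' @param cfg a \code{\link{filter_config}}.
#' @return list of class \code{placement_outcome}: \code{outcome} in
#'   \code{UNIQUE|MULTIPLE|NONE}, \code{record} (the accepted placement row
#'   when UNIQUE, else NULL), \code{n_loci}.
#' @export
classify_placement <- function(candidates, cfg = filter_config()) {
  pass <- candidates[!candidates$gapped &
                     candidates$length >= cfg$min_aln_len &
                     candidates$identity >= cfg$min_identity, , drop = FALSE]
  if (nrow(pass) == 0L)
    return(structure(list(outcome = "NONE", record = NULL, n_loci = 0L),
                     class = "placement_outcome"))
  loci <- group_loci(pass)
  n_loci <- max(loci)
  if (n_loci >= 2L && cfg$require_unique)
    return(structure(list(outcome = "MULTIPLE", record = NULL,
                          n_loci = n_loci), class = "placement_outcome"))
  ## pick the best record of the (single) locus: longest, then most identical
  best <- pass[order(-pass$length, -pass$identity), , drop = FALSE][1L, ]
  structure(list(outcome = "UNIQUE", record = best, n_loci = n_loci),
            class = "placement_outcome")
}

#' @export
print.placement_outcome <- function(x, ...) {
  cat(sprintf("<placement_outcome> %s (%d locus/loci)\n", x$outcome, x$n_loci))
  invisible(x)
}

## Cluster passing candidates into loci: same chrom+strand and >=50%
## reciprocal overlap of reference intervals join a locus.
group_loci <- function(pass) {
  n <- nrow(pass)
  grp <- integer(n)
  next_grp <- 0L
  ord <- order(pass$chrom, pass$strand, pass$ref_start)
  for (i in ord) {
    placed <- FALSE
    if (next_grp > 0L) for (g in seq_len(next_grp)) {
      members <- which(grp == g)
      j <- members[[1L]]
      if (pass$chrom[[i]] == pass$chrom[[j]] &&
          pass$strand[[i]] == pass$strand[[j]] &&
          reciprocal_overlap(pass$ref_start[[i]], pass$ref_end[[i]],
                             pass$ref_start[[j]], pass$ref_end[[j]]) >= 0.5) {
        grp[[i]] <- g; placed <- TRUE; break
      }
    }
    if (!placed) { next_grp <- next_grp + 1L; grp[[i]] <- next_grp }
  }
  grp
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- max(0L, min(e1, e2) - max(s1, s2))
  min(ov / (e1 - s1), ov / (e2 - s2))
}

#' Place a cohort of traces
#'
#' Runs \code{\link{align_trace}} + \code{\link{classify_placement}} (or
#' classifies externally supplied candidates) for every trace.
#'
#' @param traces list of \code{\link{trace_read}}.
#' @param reference a \code{\link{reference_genome}}.
#' @param cfg a \code{\link{filter_config}}.
#' @param candidates optional pre-computed candidate table from
#'   \code{\link{read_alignment_table}}; when given the internal aligner is
#'   skipped.
#' @return list with \code{placements} (data frame of accepted UNIQUE
#'   records) and \code{summary} (named counts UNIQUE/MULTIPLE/NONE).
#' @export
place_traces <- function(traces, reference, cfg = filter_config(),
                         candidates = NULL) {
  index <- if (is.null(candidates))
    build_seed_index(reference, cfg$seed_len) else NULL
  accepted <- list()
  counts <- c(UNIQUE = 0L, MULTIPLE = 0L, NONE = 0L)
  for (t in traces) {
    cand <- if (is.null(candidates)) align_trace(t, index, reference, cfg)
            else candidates[candidates$trace_id == t$trace_id, , drop = FALSE]
    res <- classify_placement(cand, cfg)
    counts[[res$outcome]] <- counts[[res$outcome]] + 1L
    if (res$outcome == "UNIQUE")
      accepted[[length(accepted) + 1L]] <- res$record
  }
  placements <- if (length(accepted)) do.call(rbind, accepted)
                else empty_placement_df()
  rownames(placements) <- NULL
  list(placements = placements, summary = counts)
}
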
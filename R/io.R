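## Readers/writers for the external formats the pipeline touches: FASTA,
## phrap-style QUAL, BED6+6 output, the 12-column tabular alignment dialect,
## and tab-separated metadata / genotype sidecars.
##
## Conventions: all genomic coordinates are 0-based half-open everywhere in
## the package and in BED output; 1-based inclusive coordinates exist only at
## the tabular-alignment boundary. Trace coordinates are 0-based in read
## orientation.

#' Read a FASTA file
#'
#' Sequences are uppercased and any letter outside \code{A,C,G,T,N} is mapped
#' to \code{N}, so downstream N-filters are the single place ambiguity is
#' handled.
#'
#' @param path FASTA file.
#' @param as \code{"traces"} returns a list of \code{\link{trace_read}};
#'   \code{"reference"} returns a \code{\link{reference_genome}}.
#' @param metadata optional data frame with columns \code{trace_id},
#'   \code{center}, \code{organism}, \code{origin} (see
#'   \code{\link{read_trace_metadata}}); traces absent from it keep
#'   \code{UNKNOWN} defaults.
#' @return See \code{as}.
#' @export
read_fasta <- function(path, as = c("traces", "reference"), metadata = NULL) {
  as <- match.arg(as)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("malformed FASTA in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (length(set) == 0L)
    stop("malformed FASTA in '", path, "': no records", call. = FALSE)
  seqs <- as.character(set)
  ## first whitespace-delimited token of the header is the id
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(seqs)))
    stop("malformed FASTA in '", path, "': empty record '",
         names(seqs)[!nzchar(seqs)][1], "'", call. = FALSE)
  if (as == "reference") return(reference_genome(seqs))
  traces <- lapply(names(seqs), function(id)
    trace_read(id, seqs[[id]]))
  names(traces) <- names(seqs)
  if (!is.null(metadata)) traces <- attach_metadata(traces, metadata)
  traces
}

#' Write traces or a reference to FASTA
#'
#' @param x list of \code{\link{trace_read}} or a
#'   \code{\link{reference_genome}}.
#' @param path output file.
#' @param width line wrap width.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  seqs <- if (inherits(x, "reference_genome")) unclass(x)
          else vapply(x, function(t) t$sequence, character(1))
  if (is.null(names(seqs)) && !inherits(x, "reference_genome"))
    names(seqs) <- vapply(x, function(t) t$trace_id, character(1))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read phred scores from a QUAL file and attach them to traces
#'
#' The QUAL dialect mirrors FASTA: a \code{>trace_id} header followed by
#' whitespace-separated integer phred scores. Traces without a QUAL record
#' keep \code{quals = NULL}.
#'
#' @param path QUAL file.
#' @param traces list of \code{\link{trace_read}} keyed by trace id.
#' @return The trace list with \code{quals} attached where matched.
#' @export
read_qual <- function(path, traces) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("malformed QUAL in '", path,
                              "': no records", call. = FALSE)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  from <- hdr + 1L
  to <- c(hdr[-1L] - 1L, length(lines))
  names(traces) <- vapply(traces, function(t) t$trace_id, character(1))
  for (i in seq_along(hdr)) {
    id <- ids[[i]]
    if (!id %in% names(traces)) next
    body <- if (from[i] <= to[i]) lines[from[i]:to[i]] else character(0)
    toks <- unlist(strsplit(paste(body, collapse = " "), "\\s+"))
    toks <- toks[nzchar(toks)]
    q <- suppressWarnings(as.integer(toks))
    if (anyNA(q))
      stop("non-integer quality token for trace '", id, "' in '", path, "'",
           call. = FALSE)
    t <- traces[[id]]
    if (length(q) != nchar(t$sequence))
      stop("trace '", id, "': ", length(q), " quality scores for ",
           nchar(t$sequence), " bases", call. = FALSE)
    t$quals <- q
    traces[[id]] <- t
  }
  traces
}

#' Write per-trace phred scores to a QUAL file
#'
#' @param traces list of \code{\link{trace_read}}; traces without quals are
#'   skipped.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_qual <- function(traces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (t in traces) {
    if (is.null(t$quals)) next
    writeLines(c(paste0(">", t$trace_id),
                 paste(t$quals, collapse = " ")), con)
  }
  invisible(path)
}

#' Read the per-trace metadata sidecar
#'
#' Tab-separated with header columns \code{trace_id}, \code{center},
#' \code{organism}, \code{origin} (\code{DNA}/\code{RNA}/\code{UNKNOWN}).
#'
#' @param path TSV file.
#' @return data frame.
#' @export
read_trace_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("trace_id", "center", "organism", "origin")
  if (!all(need %in% names(md)))
    stop("metadata table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  md$origin <- toupper(md$origin)
  md$origin[!md$origin %in% c("DNA", "RNA")] <- "UNKNOWN"
  md
}

#' Attach sidecar metadata to traces
#'
#' @param traces list of \code{\link{trace_read}}.
#' @param metadata data frame from \code{\link{read_trace_metadata}}.
#' @return Updated trace list; traces absent from the table are unchanged.
#' @export
attach_metadata <- function(traces, metadata) {
  rownames(metadata) <- metadata$trace_id
  lapply(traces, function(t) {
    if (t$trace_id %in% rownames(metadata)) {
      row <- metadata[t$trace_id, ]
      t$center <- row$center
      t$organism <- row$organism
      t$origin <- row$origin
    }
    t
  })
}

## ---- tabular alignments (12-column, BLAST outfmt-6 dialect) ----

ALN_TAB_COLS <- c("query", "subject", "pident", "length", "mismatches",
                  "gapopens", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

#' Read pre-computed ungapped alignments (12-column tabular dialect)
#'
#' Columns: query, subject, \%identity, length, mismatches, gapopens, qstart,
#' qend, sstart, send, evalue, bitscore, with 1-based inclusive coordinates;
#' \code{sstart > send} encodes a minus-strand placement. Coordinates are
#' converted to the package's 0-based half-open convention. Rows with
#' \code{gapopens > 0} are retained but flagged \code{gapped}; the placement
#' filter rejects them.
#'
#' @param path tab-separated alignment file, no header.
#' @return data frame of candidate placements with columns \code{trace_id},
#'   \code{chrom}, \code{ref_start}, \code{ref_end}, \code{trace_start},
#'   \code{trace_end}, \code{strand}, \code{length}, \code{n_mismatch},
#'   \code{identity}, \code{gapped}.
#' @export
read_alignment_table <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) != 12L)
    stop("expected 12 tab-separated columns in '", path, "', found ",
         ncol(raw), call. = FALSE)
  names(raw) <- ALN_TAB_COLS
  minus <- raw$sstart > raw$send
  data.frame(
    trace_id = as.character(raw$query),
    chrom = as.character(raw$subject),
    ref_start = ifelse(minus, raw$send, raw$sstart) - 1L,
    ref_end = ifelse(minus, raw$sstart, raw$send),
    trace_start = raw$qstart - 1L,
    trace_end = raw$qend,
    strand = ifelse(minus, "-", "+"),
    length = raw$length,
    n_mismatch = raw$mismatches,
    identity = 1 - raw$mismatches / raw$length,
    gapped = raw$gapopens > 0L,
    stringsAsFactors = FALSE
  )
}

#' Write placements back to the 12-column tabular dialect
#'
#' Inverse of \code{\link{read_alignment_table}} (identity is emitted as
#' percent; e-value and bitscore as placeholders when absent).
#'
#' @param aln placement data frame (see \code{\link{read_alignment_table}}).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_alignment_table <- function(aln, path) {
  minus <- aln$strand == "-"
  out <- data.frame(
    query = aln$trace_id,
    subject = aln$chrom,
    pident = round(100 * aln$identity, 2),
    length = aln$length,
    mismatches = aln$n_mismatch,
    gapopens = if ("gapped" %in% names(aln)) as.integer(aln$gapped) else 0L,
    qstart = aln$trace_start + 1L,
    qend = aln$trace_end,
    sstart = ifelse(minus, aln$ref_end, aln$ref_start + 1L),
    send = ifelse(minus, aln$ref_start + 1L, aln$ref_end),
    evalue = 0, bitscore = 0
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- BED6+6 mismatch output ----

BED_COLS <- c("chrom", "start", "end", "trace_id", "qual", "strand",
              "mismatch_type", "trace_pos", "run_length", "center",
              "organism", "origin")

#' Build BED6+6 rows from a mismatch table
#'
#' One row per mismatch: genomic coordinate (0-based half-open, width 1),
#' trace id, phred quality as the BED score, placement strand, then the
#' mismatch type (read orientation), position on the trace, length of the run
#' the mismatch belongs to, sequencing center, organism, and the likely
#' origin of the trace (DNA or RNA).
#'
#' @param mismatches mismatch data frame (see
#'   \code{\link{enumerate_mismatches}}) with a \code{run_length} column.
#' @param traces optional list of \code{\link{trace_read}} supplying
#'   center/organism/origin; defaults to \code{unknown}/\code{UNKNOWN}.
#' @return data frame with the 12 BED6+6 columns.
#' @export
bed_rows <- function(mismatches, traces = NULL) {
  n <- nrow(mismatches)
  center <- organism <- rep("unknown", n)
  origin <- rep("UNKNOWN", n)
  if (!is.null(traces) && n > 0L) {
    names(traces) <- vapply(traces, function(t) t$trace_id, character(1))
    tt <- traces[mismatches$trace_id]
    center <- vapply(tt, function(t) t$center, character(1))
    organism <- vapply(tt, function(t) t$organism, character(1))
    origin <- vapply(tt, function(t) t$origin, character(1))
  }
  data.frame(
    chrom = mismatches$chrom,
    start = mismatches$ref_pos,
    end = mismatches$ref_pos + 1L,
    trace_id = mismatches$trace_id,
    qual = ifelse(is.na(mismatches$qual), 0L, mismatches$qual),
    strand = mismatches$strand,
    mismatch_type = mismatches$type,
    trace_pos = mismatches$trace_pos,
    run_length = if ("run_length" %in% names(mismatches))
      mismatches$run_length else rep(NA_integer_, n),
    center = center, organism = organism, origin = origin,
    stringsAsFactors = FALSE
  )
}

#' Write BED6+6 mismatch rows
#'
#' Tab-separated, no header, sorted by (chrom, start); optionally gzipped.
#'
#' @param rows data frame from \code{\link{bed_rows}}.
#' @param path output file.
#' @param gz gzip the output.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(rows, path, gz = FALSE) {
  if (nrow(rows) > 0L) {
    if (anyNA(rows$chrom) || any(!nzchar(rows$chrom)))
      stop("BED rows with absent chrom cannot be written", call. = FALSE)
    stopifnot(all(rows$end == rows$start + 1L),
              all(rows$mismatch_type %in% MISMATCH_TYPES))
    rows <- rows[order(rows$chrom, rows$start), , drop = FALSE]
  }
  con <- if (gz) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(rows) > 0L)
    utils::write.table(rows, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6+6 mismatch file written by \code{\link{write_bed}}
#'
#' @param path BED file (plain or gzipped).
#' @return data frame with the 12 BED6+6 columns.
#' @export
read_bed <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  raw <- tryCatch(utils::read.delim(con, header = FALSE,
                                    stringsAsFactors = FALSE),
                  error = function(e) {
                    d <- as.data.frame(matrix(nrow = 0, ncol = 12))
                    d
                  })
  if (ncol(raw) == 12L) names(raw) <- BED_COLS
  raw
}

#' Read an interval annotation (BED3+) into an interval set
#'
#' @param path BED file: chrom, start, end, optional name/label.
#' @return \code{GRanges} with a \code{label} metadata column.
#' @export
read_intervals <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 3L) stop("interval BED needs >= 3 columns", call. = FALSE)
  interval_set(raw[[1]], raw[[2]], raw[[3]],
               label = if (ncol(raw) >= 4L) raw[[4]] else NA_character_)
}

#' Construct an interval set (0-based half-open in, GRanges out)
#'
#' @param chrom,start,end vectors describing 0-based half-open intervals.
#' @param label optional labels (e.g. repeat family).
#' @return \code{GRanges}.
#' @export
interval_set <- function(chrom, start, end, label = NA_character_) {
  stopifnot(all(start < end))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end))
  gr$label <- label
  gr
}

#' Read a genotype table into a site-by-individual matrix
#'
#' Tab-separated with header: \code{site_id}, \code{ref}, \code{alt}, then
#' one column per individual holding \code{ref/ref}, \code{ref/alt},
#' \code{alt/alt} or \code{missing}.
#'
#' @param path TSV file.
#' @return list with \code{sites} (data frame: site_id, ref, alt) and
#'   \code{geno} (character matrix, rownames = site ids).
#' @export
read_genotype_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("site_id", "ref", "alt")
  if (!all(need %in% names(raw)))
    stop("genotype table must start with columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  geno <- as.matrix(raw[, setdiff(names(raw), need), drop = FALSE])
  rownames(geno) <- raw$site_id
  list(sites = raw[, need], geno = geno)
}
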
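## Shared fixture builders and independent oracles, all generated in code.

## mismatch table from parallel vectors (defaults fill plausible fields)
make_mm <- function(types, trace_pos, qual = NA_integer_,
                    trace_id = "t1", trace_motif = "CAC",
                    ref_motif = "CGC", chrom = "chr1",
                    ref_pos = trace_pos, strand = "+") {
  n <- length(types)
  data.frame(
    trace_id = rep_len(trace_id, n), chrom = rep_len(chrom, n),
    ref_pos = ref_pos, trace_pos = trace_pos,
    ref_base = substr(types, 1, 1), trace_base = substr(types, 3, 3),
    type = types, qual = rep_len(qual, n),
    trace_motif = rep_len(trace_motif, n),
    ref_motif = rep_len(ref_motif, n),
    strand = rep_len(strand, n), stringsAsFactors = FALSE)
}

## exhaustive run oracle: a contiguous block [i, j] of equal types is a
## maximal run iff it cannot be extended on either side; O(n^2) scan,
## independent of the rle-based implementation
oracle_runs <- function(types, min_run) {
  n <- length(types)
  out <- list()
  for (i in seq_len(n)) for (j in i:n) {
    if (length(unique(types[i:j])) != 1L) next
    if (i > 1L && types[i - 1L] == types[i]) next
    if (j < n && types[j + 1L] == types[j]) next
    if (j - i + 1L >= min_run)
      out[[length(out) + 1L]] <- c(i, j)
  }
  out
}

## enumeration oracle for the two-sided Fisher test: probabilities from
## products of binomial coefficients, never from dhyper
enum_fisher <- function(a, b, c, d) {
  m1 <- a + b; n1 <- a + c; n2 <- b + d; N <- a + b + c + d
  if (m1 == 0 || c + d == 0 || n1 == 0 || n2 == 0) return(1)
  xs <- max(0, m1 - n2):min(m1, n1)
  probs <- vapply(xs, function(x)
    choose(n1, x) * choose(n2, m1 - x) / choose(N, m1), numeric(1))
  p_obs <- choose(n1, a) * choose(n2, m1 - a) / choose(N, m1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## naive per-column mismatch walker, independent of enumerate_mismatches
walker_mismatches <- function(aln, reference, trace) {
  refwin <- ref_fetch(reference, aln$chrom, aln$ref_start, aln$ref_end)
  read <- trace$sequence
  L <- nchar(read)
  out <- list()
  for (k in seq_len(nchar(refwin))) {
    rb <- substr(refwin, k, k)
    if (aln$strand == "+") {
      tp <- aln$trace_start + k - 1L
      tb <- substr(read, tp + 1L, tp + 1L)
      rb_read <- rb
    } else {
      tp <- aln$trace_end - k
      tb <- substr(read, tp + 1L, tp + 1L)
      rb_read <- chartr("ACGTN", "TGCAN", rb)
    }
    if (rb_read != tb && rb_read != "N" && tb != "N")
      out[[length(out) + 1L]] <- data.frame(
        ref_pos = aln$ref_start + k - 1L, trace_pos = tp,
        type = paste0(rb_read, ">", tb), stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(ref_pos = integer(0), trace_pos = integer(0),
                  type = character(0))
}

## random DNA string
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

## clean simulation settings: no variants, no planted signals, flat phred
## `qual` everywhere (90 ~ zero base errors)
clean_sim <- function(seed, n_traces, qual = 90L, ...) {
  sim_config(seed = seed, n_traces = n_traces, mutation_rate = 0,
             qual_high = qual, qual_tail_end = qual,
             rna_fraction = 0, editing = list(fraction = 0),
             dna_editing = list(fraction = 0),
             artifact = list(fraction = 0), ...)
}
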
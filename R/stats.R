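## Exact enrichment statistics: two-sided Fisher test computed in log space,
## upstream-context profiles, repeat-interval overlap, SNP monomorphism, and
## editing-rate estimates.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Minimum-likelihood two-sided p: the sum, over all tables with the
#' observed margins, of hypergeometric probabilities no larger than that of
#' the observed table (with a relative tolerance of 1e-7 on the observed
#' probability, guarding against ties lost to rounding). Probabilities are
#' evaluated in log space via the log-gamma function, so tables with entries
#' of order 1e5 remain exact. A zero margin gives p = 1.
#'
#' @param a,b,c,d the 2x2 counts, rows = focal set vs background: a,b on the
#'   first row, c,d on the second. \code{a} may also be a 2x2 matrix.
#' @return the two-sided p-value.
#' @examples
#' fisher_exact_two_sided(247, 129, 91120, 79401)  # 1.7e-06
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  if (is.matrix(a)) { b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1] }
  stopifnot(length(a) == 1L, a >= 0, b >= 0, c >= 0, d >= 0,
            a + b + c + d > 0)
  m1 <- a + b; m2 <- c + d        # row margins
  n1 <- a + c; n2 <- b + d        # column margins
  if (m1 == 0 || m2 == 0 || n1 == 0 || n2 == 0) return(1)
  ## support of the [1,1] cell given the margins
  x <- max(0, m1 - n2):min(m1, n1)
  logp <- stats::dhyper(x, n1, n2, m1, log = TRUE)
  log_obs <- stats::dhyper(a, n1, n2, m1, log = TRUE)
  p <- sum(exp(logp[logp <= log_obs + log1p(1e-7)]))
  min(1, p)
}

#' Upstream-nucleotide context profile of editing sites
#'
#' ADAR-edited adenosines are depleted of G immediately 5' of the edited
#' base. The neighbour is read in editing-sense orientation: for an A>G site
#' on the plus strand of editing sense, the reference base at
#' \code{ref_pos - 1}; for a site whose genomic record is T>C (editing sense
#' on the other strand), the complement of the reference base at
#' \code{ref_pos + 1}. Sites are supplied with their read-orientation type
#' and placement strand; the genomic-sense type is derived internally.
#' Sites with an N neighbour are excluded from the denominator; sites at a
#' contig edge are excluded with a warning.
#'
#' @param sites data frame with columns \code{chrom}, \code{ref_pos},
#'   \code{type} (read orientation, \code{A>G} or \code{T>C}) and
#'   \code{strand} (\code{+}/\code{-}; default \code{+} when absent).
#' @param reference a \code{\link{reference_genome}}.
#' @return list of class \code{context_profile}: \code{counts} (named A/C/G/T),
#'   \code{fractions} (summing to 1), \code{n} (denominator),
#'   \code{n_excluded}.
#' @export
upstream_context_profile <- function(sites, reference) {
  if (!"strand" %in% names(sites)) sites$strand <- "+"
  stopifnot(all(sites$type %in% c("A>G", "T>C")))
  ## genomic-sense type: flip the pair for minus-strand placements
  genomic_AG <- (sites$type == "A>G") == (sites$strand == "+")
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  n_excluded <- 0L
  seqs <- unclass(reference)
  for (i in seq_len(nrow(sites))) {
    chromseq <- seqs[[sites$chrom[[i]]]]
    L <- nchar(chromseq)
    pos <- sites$ref_pos[[i]]
    if (genomic_AG[[i]]) {
      if (pos - 1L < 0L) { n_excluded <- n_excluded + 1L; next }
      nb <- substr(chromseq, pos, pos)
    } else {
      if (pos + 1L >= L) { n_excluded <- n_excluded + 1L; next }
      nb <- comp_chars(substr(chromseq, pos + 2L, pos + 2L))
    }
    if (nb == "N") { n_excluded <- n_excluded + 1L; next }
    counts[[nb]] <- counts[[nb]] + 1L
  }
  if (n_excluded > 0L)
    warning(n_excluded, " site(s) excluded (contig edge or N neighbour)")
  n <- sum(counts)
  structure(list(counts = counts,
                 fractions = if (n > 0) counts / n else counts * NA_real_,
                 n = n, n_excluded = n_excluded),
            class = "context_profile")
}

#' @export
print.context_profile <- function(x, ...) {
  cat("<context_profile> n =", x$n, "\n")
  print(round(100 * x$fractions, 2))
  invisible(x)
}

#' Interval-overlap enrichment of sites
#'
#' Fraction of sites falling inside any interval of the set, with a
#' one-sided binomial tail p-value P(X >= k | n, genome_fraction) against
#' the genomic background fraction the intervals occupy.
#'
#' @param sites data frame with \code{chrom} and \code{ref_pos} (0-based).
#' @param intervals a \code{GRanges} from \code{\link{interval_set}}.
#' @param genome_fraction fraction of the genome covered by the interval
#'   class, in (0, 1).
#' @return list: \code{overlap_fraction}, \code{n_inside}, \code{n},
#'   \code{p_value}.
#' @export
interval_overlap_enrichment <- function(sites, intervals, genome_fraction) {
  stopifnot(genome_fraction > 0, genome_fraction < 1)
  if (nrow(sites) == 0L) stop("no sites supplied", call. = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$ref_pos + 1L, width = 1L))
  inside <- IRanges::overlapsAny(gr, intervals)
  k <- sum(inside); n <- length(inside)
  p <- stats::pbinom(k - 1L, n, genome_fraction, lower.tail = FALSE)
  list(overlap_fraction = k / n, n_inside = k, n = n, p_value = p)
}

#' Fraction of sites monomorphic for the reference allele
#'
#' A catalogued SNP site is monomorphic-reference when every non-missing
#' genotype across the panel is \code{ref/ref}. Reports the fraction over
#' the supplied sites and, when a background (monomorphic, polymorphic)
#' pair is given, the enrichment versus that background via
#' \code{\link{fisher_exact_two_sided}}.
#'
#' @param site_ids site identifiers to assess (subset of the matrix rows);
#'   sites absent from the matrix are excluded and tallied.
#' @param geno character matrix sites x individuals with entries
#'   \code{ref/ref}, \code{ref/alt}, \code{alt/alt}, \code{missing}.
#' @param background optional integer pair \code{c(n_monomorphic, n_total)}
#'   describing the comparison SNP set.
#' @return list: \code{fraction}, \code{n_monomorphic}, \code{n},
#'   \code{n_excluded}, and when background is given \code{p_value} and
#'   \code{table} (the 2x2 used).
#' @export
monomorphic_reference_fraction <- function(site_ids, geno,
                                           background = NULL) {
  present <- site_ids %in% rownames(geno)
  n_excluded <- sum(!present)
  ids <- site_ids[present]
  g <- geno[ids, , drop = FALSE]
  known <- g != "missing"
  mono <- rowSums((g == "ref/ref") | !known) == ncol(g) & rowSums(known) > 0L
  k <- sum(mono); n <- length(ids)
  out <- list(fraction = if (n > 0) k / n else NA_real_,
              n_monomorphic = k, n = n, n_excluded = n_excluded)
  if (!is.null(background)) {
    tab <- matrix(c(k, n - k,
                    background[[1L]], background[[2L]] - background[[1L]]),
                  nrow = 2, byrow = TRUE)
    out$p_value <- fisher_exact_two_sided(tab)
    out$table <- tab
  }
  out
}

#' Number of distinct reference positions covered by placements
#'
#' Overlapping placements count shared bases once.
#'
#' @param placements accepted placement table (\code{chrom},
#'   \code{ref_start}, \code{ref_end}).
#' @return integer, total unique covered bp.
#' @export
unique_covered_bp <- function(placements) {
  if (nrow(placements) == 0L) return(0L)
  gr <- GenomicRanges::GRanges(
    seqnames = placements$chrom,
    ranges = IRanges::IRanges(start = placements$ref_start + 1L,
                              end = placements$ref_end))
  sum(IRanges::width(GenomicRanges::reduce(gr)))
}

#' Editing rate per unique covered base pair
#'
#' @param n_editing_mismatches count of editing-type mismatches.
#' @param unique_bp distinct reference positions covered by the relevant
#'   (e.g. RNA-origin) accepted placements; must be positive.
#' @return list: \code{rate} (per bp) and \code{per_100kb}.
#' @export
editing_rate <- function(n_editing_mismatches, unique_bp) {
  if (unique_bp <= 0) stop("unique_bp must be positive", call. = FALSE)
  rate <- n_editing_mismatches / unique_bp
  list(rate = rate, per_100kb = rate * 1e5)
}

#' Percentage of editing-type (A>G + T>C) clusters
#'
#' @param tally data frame from \code{\link{tally_by_type}}; the \code{count}
#'   column (or \code{rna_count} when \code{use_rna}) is used.
#' @param use_rna use the RNA-origin counts.
#' @return percentage 100 * (A>G + T>C) / total over the five tally rows.
#' @export
editing_type_fraction <- function(tally, use_rna = FALSE) {
  col <- if (use_rna) "rna_count" else "count"
  counts <- tally[[col]]
  names(counts) <- tally$type
  total <- sum(counts)
  if (total == 0) stop("empty tally", call. = FALSE)
  100 * (counts[["A>G"]] + counts[["T>C"]]) / total
}
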
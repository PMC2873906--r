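test_that("two-sided Fisher reproduces the printed editing p-values", {
  ## human DNA-editing clusters vs genome background; printed 0.0000017
  p_hs <- fisher_exact_two_sided(247, 129, 91120, 79401)
  expect_lt(abs(p_hs - 1.7e-6), 1e-7)
  ## mouse IAP clusters vs genome background; printed 0.00018
  p_mm <- fisher_exact_two_sided(114, 49, 9799, 7860)
  expect_lt(abs(p_mm - 1.8e-4), 1e-5)
})

test_that("Fisher degenerate and symmetry cases", {
  expect_equal(fisher_exact_two_sided(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_two_sided(3, 7, 3, 7), 1)
  expect_equal(fisher_exact_two_sided(0, 0, 10, 20), 1)   # zero margin
  expect_equal(fisher_exact_two_sided(0, 10, 0, 20), 1)

  ## invariance under row swap, column swap and transpose
  p <- fisher_exact_two_sided(12, 3, 5, 20)
  expect_equal(fisher_exact_two_sided(5, 20, 12, 3), p)
  expect_equal(fisher_exact_two_sided(3, 12, 20, 5), p)
  expect_equal(fisher_exact_two_sided(12, 5, 3, 20), p)
})

test_that("Fisher agrees with enumeration and fisher.test on small tables", {
  set.seed(91)
  for (rep in 1:300) {
    n <- sample(1:30, 1)
    cuts <- sort(sample(0:n, 3, replace = TRUE))
    a <- cuts[1]; b <- cuts[2] - cuts[1]; c <- cuts[3] - cuts[2]
    d <- n - cuts[3]
    p <- fisher_exact_two_sided(a, b, c, d)
    expect_equal(p, enum_fisher(a, b, c, d), tolerance = 1e-12)
    if (min(a + b, c + d, a + c, b + d) > 0)
      expect_equal(p, stats::fisher.test(matrix(c(a, c, b, d), 2))$p.value,
                   tolerance = 1e-9)
  }
})

test_that("Fisher stays exact for archive-scale counts", {
  ## cross-check the log-space path against fisher.test on large tables
  expect_equal(fisher_exact_two_sided(247, 129, 91120, 79401),
               stats::fisher.test(matrix(c(247, 91120, 129, 79401), 2))$p.value,
               tolerance = 1e-9)
})

test_that("upstream context is read in editing-sense orientation", {
  ## layout (0-based): A A G A T T G C G A
  ##   pos 3 = A>G site on +, upstream = pos 2
  ##   pos 5 = genomic T>C site, sense neighbour = comp(pos 6)
  ref <- reference_genome(c(chr1 = "AAGATTGCGA"))
  sites <- data.frame(chrom = "chr1", ref_pos = c(3L, 5L),
                      type = c("A>G", "T>C"), strand = "+",
                      stringsAsFactors = FALSE)
  prof <- upstream_context_profile(sites, ref)
  ## A>G at 3: base at 2 is G; T>C at 5: base at 6 is G -> complement C
  expect_equal(prof$counts[["G"]], 1L)
  expect_equal(prof$counts[["C"]], 1L)
  expect_equal(prof$n, 2L)
  expect_equal(sum(prof$fractions), 1)

  ## a minus-strand A>G placement is a genomic T>C site
  sites_m <- data.frame(chrom = "chr1", ref_pos = 5L, type = "A>G",
                        strand = "-", stringsAsFactors = FALSE)
  prof_m <- upstream_context_profile(sites_m, ref)
  expect_equal(prof_m$counts[["C"]], 1L)

  ## contig-edge sites are excluded with a warning
  edge <- data.frame(chrom = "chr1", ref_pos = 0L, type = "A>G",
                     strand = "+", stringsAsFactors = FALSE)
  expect_warning(pe <- upstream_context_profile(edge, ref), "excluded")
  expect_equal(pe$n, 0L)
})

test_that("ignoring strand orientation destroys a planted G-depletion", {
  ## genomic T>C sites whose sense-upstream (comp of pos+1) is never G but
  ## whose naive plus-strand left neighbour always is
  set.seed(92)
  n <- 60L
  chunk <- vapply(seq_len(n), function(i) "GTA", "")   # G T A repeated
  ref <- reference_genome(c(chr1 = paste(chunk, collapse = "")))
  pos <- 3L * (seq_len(n) - 1L) + 1L                   # the T's, 0-based
  sites <- data.frame(chrom = "chr1", ref_pos = pos, type = "T>C",
                      strand = "+", stringsAsFactors = FALSE)
  correct <- upstream_context_profile(sites, ref)
  expect_equal(correct$fractions[["G"]], 0)            # comp(A) = T
  naive <- upstream_context_profile(
    transform(sites, type = "A>G"), ref)               # wrong orientation
  expect_equal(naive$fractions[["G"]], 1)
})

test_that("interval overlap enrichment uses the binomial tail", {
  ## 9 of 10 sites inside intervals covering 10% of a toy genome
  iv <- interval_set(rep("chr1", 2), c(100L, 500L), c(200L, 600L))
  sites <- data.frame(chrom = "chr1",
                      ref_pos = c(100:104, 150:153, 900L),
                      stringsAsFactors = FALSE)
  res <- interval_overlap_enrichment(sites, iv, genome_fraction = 0.1)
  expect_equal(res$overlap_fraction, 0.9)
  ## closed-form tail: C(10,9) 0.1^9 0.9 + 0.1^10
  expect_equal(res$p_value, 10 * 0.1^9 * 0.9 + 0.1^10, tolerance = 1e-12)

  none <- interval_overlap_enrichment(
    data.frame(chrom = "chr1", ref_pos = 900:909), iv, 0.1)
  expect_equal(none$overlap_fraction, 0)
  expect_equal(none$p_value, 1)

  expect_error(interval_overlap_enrichment(sites[0, ], iv, 0.1), "no sites")

  ## fragmentation invariance: splitting an interval never changes
  ## membership
  iv_frag <- interval_set(rep("chr1", 4), c(100L, 150L, 500L, 550L),
                          c(150L, 200L, 550L, 600L))
  res_frag <- interval_overlap_enrichment(sites, iv_frag, 0.1)
  expect_equal(res_frag$overlap_fraction, res$overlap_fraction)
})

test_that("monomorphic-reference logic follows the genotype definition", {
  geno <- rbind(
    s1 = c("ref/ref", "ref/ref", "missing"),
    s2 = c("ref/ref", "ref/alt", "ref/ref"),
    s3 = c("alt/alt", "ref/ref", "ref/ref"),
    s4 = c("ref/ref", "ref/ref", "ref/ref"))
  res <- monomorphic_reference_fraction(paste0("s", 1:4), geno)
  expect_equal(res$n_monomorphic, 2L)                 # s1, s4
  expect_equal(res$fraction, 0.5)

  ## a single ref/alt individual breaks monomorphism
  one <- monomorphic_reference_fraction("s2", geno)
  expect_equal(one$n_monomorphic, 0L)

  ## absent sites are excluded and tallied
  res2 <- monomorphic_reference_fraction(c("s1", "nope"), geno)
  expect_equal(res2$n_excluded, 1L)
  expect_equal(res2$n, 1L)

  ## background comparison feeds the exact test
  res3 <- monomorphic_reference_fraction(paste0("s", 1:4), geno,
                                         background = c(100L, 1000L))
  expect_equal(res3$table[1, ], c(2, 2))
  expect_equal(res3$p_value,
               fisher_exact_two_sided(2, 2, 100, 900))
})

test_that("editing rate counts unique covered bases once", {
  expect_equal(editing_rate(10, 1e6)$per_100kb, 1)
  expect_error(editing_rate(10, 0), "positive")

  ## overlapping placements share bases
  pl <- data.frame(chrom = "chr1", ref_start = c(0L, 50L),
                   ref_end = c(100L, 150L))
  expect_equal(unique_covered_bp(pl), 150L)

  ## set-union oracle on simulated placements
  sim <- simulate_cohort(clean_sim(seed = 93, n_traces = 100))
  placed <- place_traces(sim$traces, sim$reference)
  got <- unique_covered_bp(placed$placements)
  oracle <- length(unique(unlist(lapply(
    seq_len(nrow(placed$placements)), function(i)
      seq(placed$placements$ref_start[i],
          placed$placements$ref_end[i] - 1L)))))
  expect_equal(got, oracle)
})

test_that("editing-type share reproduces the printed cohort percentages", {
  tal_hs <- data.frame(type = c("G>A", "C>T", "A>G", "T>C", "other"),
                       count = c(82L, 72L, 188L, 419L, 8L))
  expect_equal(round(editing_type_fraction(tal_hs)), 79)
  tal_xt <- data.frame(type = c("G>A", "C>T", "A>G", "T>C", "other"),
                       count = c(202L, 262L, 1289L, 1066L, 28L))
  expect_equal(round(editing_type_fraction(tal_xt)), 83)
  expect_error(editing_type_fraction(transform(tal_hs, count = 0L)), "empty")
  zero_edit <- data.frame(type = c("G>A", "C>T", "A>G", "T>C", "other"),
                          count = c(5L, 5L, 0L, 0L, 1L))
  expect_equal(editing_type_fraction(zero_edit), 0)
})
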
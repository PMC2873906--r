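runs_of <- function(types, pos, qual, trace_id = "t1") {
  find_runs(make_mm(types, pos, qual = qual, trace_id = trace_id),
            scan_config(min_run = 3L, min_span_bp = 0L))
}

test_that("high-quality selection needs two phred-40 mismatches 100 bp apart", {
  cfg <- quality_set_config("HIGH")

  ok <- runs_of(rep("G>A", 3), c(10, 60, 150), c(45, 20, 41))
  sel <- select_enriched(ok, cfg)
  expect_equal(nrow(sel), 1L)
  expect_equal(sel$n_reported, 2L)                 # only passing mismatches
  expect_equal(sel$reported[[1]]$qual, c(45L, 41L))

  ## same quals, pair separation 80 < 100 -> excluded
  near <- runs_of(rep("G>A", 3), c(10, 60, 90), c(45, 20, 41))
  expect_equal(nrow(select_enriched(near, cfg)), 0L)

  ## only one phred-40 mismatch -> excluded
  one <- runs_of(rep("G>A", 3), c(10, 60, 150), c(45, 20, 39))
  expect_equal(nrow(select_enriched(one, cfg)), 0L)

  ## traces without quals are excluded with a warning
  nq <- runs_of(rep("G>A", 3), c(10, 60, 150), NA_integer_)
  expect_warning(out <- select_enriched(nq, cfg), "without quality")
  expect_equal(nrow(out), 0L)
})

test_that("LOW mirrors HIGH with the predicate inverted", {
  low <- quality_set_config("LOW")
  expect_equal(low$q_threshold, 10L)
  art <- runs_of(rep("G>A", 4), c(5, 80, 200, 300), c(4, 25, 8, 9))
  sel <- select_enriched(art, low)
  expect_equal(nrow(sel), 1L)
  expect_equal(sel$reported[[1]]$qual, c(4L, 8L, 9L))

  ## a fully high-quality run can never satisfy LOW, nor vice versa
  hi <- runs_of(rep("A>G", 3), c(10, 120, 260), c(44, 47, 42))
  expect_equal(nrow(select_enriched(hi, low)), 0L)
  lo <- runs_of(rep("G>A", 3), c(10, 120, 260), c(4, 7, 2))
  expect_equal(nrow(select_enriched(lo, quality_set_config("HIGH"))), 0L)
})

test_that("selection is monotone under a +1 quality shift", {
  set.seed(71)
  cfg <- quality_set_config("HIGH")
  for (rep in 1:40) {
    n <- sample(3:8, 1)
    pos <- sort(sample(0:600, n))
    qual <- sample(30:45, n, replace = TRUE)
    runs <- runs_of(rep("A>G", n), pos, qual)
    runs_up <- runs_of(rep("A>G", n), pos, pmin(qual + 1L, 93L))
    if (nrow(select_enriched(runs, cfg)) == 1L)
      expect_equal(nrow(select_enriched(runs_up, cfg)), 1L)
  }
})

test_that("a trace counts once per qualifying run type", {
  cfg <- quality_set_config("HIGH")
  mm <- rbind(
    make_mm(rep("G>A", 3), c(10, 120, 260), qual = 45L),
    make_mm(rep("A>G", 3), c(300, 420, 560), qual = 45L),
    make_mm(rep("G>A", 3), c(600, 700, 830), qual = 45L))
  runs <- find_runs(mm, scan_config(min_run = 3L, min_span_bp = 0L))
  expect_equal(nrow(runs), 3L)
  sel <- select_enriched(runs, cfg)
  expect_equal(nrow(sel), 2L)                     # one row per type
  expect_setequal(sel$type, c("G>A", "A>G"))
})

test_that("type tally reproduces the summary-table shape", {
  ## RNA-origin counts of the human genome row; the five-way tally must
  ## sum to the cohort size
  counts <- c("G>A" = 82L, "C>T" = 72L, "A>G" = 188L, "T>C" = 419L,
              "G>C" = 8L)
  enr <- data.frame(
    trace_id = sprintf("t%03d", seq_len(sum(counts))),
    type = rep(names(counts), counts),
    origin = "RNA", stringsAsFactors = FALSE)
  tal <- tally_by_type(enr, by_origin = TRUE)
  expect_equal(tal$type, c("G>A", "C>T", "A>G", "T>C", "other"))
  expect_equal(tal$count, c(82L, 72L, 188L, 419L, 8L))
  expect_equal(sum(tal$rna_count), 769L)

  empty <- tally_by_type(enr[0, ])
  expect_equal(empty$count, rep(0L, 5))
})

test_that("tally matches an independent group-by on 1,000 random rows", {
  set.seed(72)
  enr <- data.frame(
    trace_id = sprintf("t%04d", 1:1000),
    type = sample(editscan:::MISMATCH_TYPES, 1000, replace = TRUE),
    origin = sample(c("DNA", "RNA"), 1000, replace = TRUE),
    stringsAsFactors = FALSE)
  tal <- tally_by_type(enr, by_origin = TRUE)
  ref_tab <- table(enr$type)
  for (ty in c("G>A", "C>T", "A>G", "T>C"))
    expect_equal(tal$count[tal$type == ty], unname(ref_tab[[ty]]))
  others <- ref_tab[setdiff(names(ref_tab),
                            c("G>A", "C>T", "A>G", "T>C"))]
  expect_equal(tal$count[tal$type == "other"], max(others))
  rna_tab <- table(enr$type[enr$origin == "RNA"])
  expect_equal(tal$rna_count[tal$type == "A>G"], unname(rna_tab[["A>G"]]))
})

test_that("run-length spectrum normalises and matches a recount", {
  set.seed(73)
  runs <- do.call(rbind, lapply(1:200, function(i) {
    n <- sample(1:8, 1)
    ty <- sample(c("G>A", "C>T", "A>G", "T>C"), 1)
    find_runs(make_mm(rep(ty, n), sort(sample(0:500, n)),
                      trace_id = sprintf("t%03d", i)),
              scan_config(min_run = 1L, min_span_bp = 0L))
  }))
  sp <- spectrum_by_run_length(runs, max_k = 8L)
  for (k in 1:8) {
    if (all(is.na(sp[, k]))) next
    expect_equal(sum(sp[, k]), 100, tolerance = 1e-10)
    recount <- table(factor(runs$type[runs$length >= k],
                            levels = rownames(sp)))
    expect_equal(sp[, k], 100 * as.numeric(recount) / sum(recount),
                 ignore_attr = TRUE, tolerance = 1e-10)
  }
  ## single-type degenerate case: 100% at every k up to its length
  mono <- runs[runs$type == "G>A", ]
  spm <- spectrum_by_run_length(mono, max_k = max(mono$length))
  expect_true(all(spm["G>A", !is.na(spm["G>A", ])] == 100))
})

test_that("quality spectrum bins are closed-left open-right", {
  r40 <- runs_of(rep("A>G", 3), c(10, 120, 260), c(40, 40, 40))
  sp <- spectrum_by_quality(r40, bins = c(0, 40, 94))
  expect_true(is.na(sp["A>G", 1]))
  expect_equal(sp["A>G", 2], 100)

  r39 <- runs_of(rep("A>G", 3), c(10, 120, 260), c(39, 39, 39))
  sp <- spectrum_by_quality(r39, bins = c(0, 40, 94))
  expect_equal(sp["A>G", 1], 100)
  expect_true(is.na(sp["A>G", 2]))
})
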
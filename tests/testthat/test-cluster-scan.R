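## helpers to build a one-trace placement against a small reference
place_one <- function(ref, trace, cfg = filter_config(min_aln_len = 100L,
                                                      seed_len = 30L)) {
  idx <- build_seed_index(ref, cfg$seed_len)
  res <- classify_placement(align_trace(trace, idx, ref, cfg), cfg)
  expect_equal(res$outcome, "UNIQUE")
  res$record
}

test_that("perfect placements yield no mismatches", {
  set.seed(61)
  ref <- reference_genome(c(chr1 = rand_seq(2000)))
  tr <- trace_read("p", ref_fetch(ref, "chr1", 300, 800))
  aln <- place_one(ref, tr)
  expect_equal(nrow(enumerate_mismatches(aln, ref, tr)), 0L)
})

test_that("minus-strand mismatches are reported in read orientation", {
  set.seed(62)
  ## plant a genomic C sequenced as T; the minus-strand read then shows
  ## ref G aligned to trace A, i.e. type G>A
  ch <- seq_chars(rand_seq(1200))
  ch[[600]] <- "C"
  ref <- reference_genome(c(chr1 = paste(ch, collapse = "")))
  win <- seq_chars(ref_fetch(ref, "chr1", 350, 850))
  win[[250]] <- "T"                      # genomic offset 599, 0-based
  tr <- trace_read("m", revcomp(paste(win, collapse = "")))
  aln <- place_one(ref, tr)
  expect_equal(aln$strand, "-")
  mm <- enumerate_mismatches(aln, ref, tr)
  expect_equal(nrow(mm), 1L)
  expect_equal(mm$type, "G>A")
  expect_equal(mm$ref_pos, 599L)
  expect_equal(mm$trace_pos, 500L - 250L)  # read position of the change
})

test_that("mismatch columns containing N are skipped", {
  set.seed(63)
  ref <- reference_genome(c(chr1 = rand_seq(1000)))
  win <- seq_chars(ref_fetch(ref, "chr1", 200, 700))
  win[[480]] <- "N"
  tr <- trace_read("n", paste(win, collapse = ""))
  aln <- place_one(ref, tr)
  ## the N itself is not a mismatch; extension simply stops there
  expect_equal(nrow(enumerate_mismatches(aln, ref, tr)), 0L)
})

test_that("an independent column walker agrees on simulated placements", {
  sim <- simulate_cohort(sim_config(seed = 64, n_traces = 60))
  placed <- place_traces(sim$traces, sim$reference)
  traces <- sim$traces
  names(traces) <- vapply(traces, `[[`, "", "trace_id")
  expect_gt(nrow(placed$placements), 40)
  for (i in seq_len(nrow(placed$placements))) {
    aln <- placed$placements[i, ]
    mm <- enumerate_mismatches(aln, sim$reference, traces[[aln$trace_id]])
    wk <- walker_mismatches(aln, sim$reference, traces[[aln$trace_id]])
    wk <- wk[order(wk$trace_pos), ]
    expect_equal(mm$trace_pos, wk$trace_pos)
    expect_equal(mm$ref_pos[order(mm$ref_pos)], sort(wk$ref_pos))
    expect_equal(mm$type, wk$type[order(wk$trace_pos)], ignore_attr = TRUE)
  }
})

test_that("find_runs returns maximal same-type blocks above min_run", {
  cfg <- scan_config(min_run = 3L, min_span_bp = 0L)

  mm <- make_mm(c("G>A", "G>A", "G>A", "C>T"), c(10, 40, 80, 120))
  runs <- find_runs(mm, cfg)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$type, "G>A")
  expect_equal(runs$length, 3L)

  ## an intervening different type breaks the run: only the trailing block
  ## of three survives
  mm <- make_mm(c("G>A", "G>A", "C>T", "G>A", "G>A", "G>A"),
                c(10, 30, 50, 70, 90, 200))
  runs <- find_runs(mm, cfg)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$first_pos, 70L)
  expect_equal(runs$length, 3L)

  ## span arithmetic
  mm <- make_mm(rep("G>A", 5), c(10, 60, 120, 180, 250))
  runs <- find_runs(mm, scan_config(min_run = 5L, min_span_bp = 0L))
  expect_equal(runs$length, 5L)
  expect_equal(runs$span_bp, 240L)
})

test_that("every mismatch belongs to exactly one maximal run", {
  set.seed(65)
  for (rep in 1:50) {
    n <- sample(1:12, 1)
    types <- sample(c("G>A", "C>T", "A>G"), n, replace = TRUE)
    mm <- make_mm(types, sort(sample(0:400, n)))
    runs <- find_runs(mm, scan_config(min_run = 1L, min_span_bp = 0L))
    expect_equal(sum(runs$length), n)
    got <- do.call(rbind, runs$members)
    expect_equal(sort(got$trace_pos), mm$trace_pos)
  }
})

test_that("find_runs agrees with the exhaustive block oracle", {
  ## all type sequences of length <= 6 over 3 types, both thresholds
  types3 <- c("G>A", "C>T", "A>G")
  for (n in 1:6) {
    grid <- expand.grid(rep(list(types3), n), stringsAsFactors = FALSE)
    for (r in seq_len(nrow(grid))) {
      types <- unlist(grid[r, ], use.names = FALSE)
      mm <- make_mm(types, seq_along(types) * 10L)
      for (min_run in c(1L, 2L, 3L)) {
        runs <- find_runs(mm, scan_config(min_run = min_run,
                                          min_span_bp = 0L))
        oracle <- oracle_runs(types, min_run)
        expect_equal(nrow(runs), length(oracle))
        if (length(oracle))
          expect_equal(runs$length,
                       vapply(oracle, function(b) b[2] - b[1] + 1L,
                              integer(1)))
      }
    }
  }
})

test_that("reverse-complementing both sequences complements the run types", {
  sim <- simulate_cohort(sim_config(seed = 66, n_traces = 30))
  placed <- place_traces(sim$traces, sim$reference)
  traces <- sim$traces
  names(traces) <- vapply(traces, `[[`, "", "trace_id")
  scan <- scan_cohort(placed$placements, sim$reference, traces,
                      scan_config(min_run = 2L, min_span_bp = 0L))
  expect_gt(nrow(scan$runs), 3)

  rc_ref <- reference_genome(c(chr1 = revcomp(unclass(sim$reference)[[1]])))
  rc_traces <- lapply(traces, function(t) {
    t$sequence <- revcomp(t$sequence)
    if (!is.null(t$quals)) t$quals <- rev(t$quals)
    t
  })
  placed_rc <- place_traces(rc_traces, rc_ref)
  scan_rc <- scan_cohort(placed_rc$placements, rc_ref, rc_traces,
                         scan_config(min_run = 2L, min_span_bp = 0L))
  comp_type <- function(ty) chartr("ACGT", "TGCA", ty)
  a <- sort(paste(scan$runs$trace_id, comp_type(scan$runs$type),
                  scan$runs$length))
  b <- sort(paste(scan_rc$runs$trace_id, scan_rc$runs$type,
                  scan_rc$runs$length))
  expect_equal(b, a)
})

test_that("span filter keeps >= 100 bp and is idempotent", {
  cfg <- scan_config(min_run = 2L, min_span_bp = 100L)
  near <- find_runs(make_mm(rep("G>A", 2), c(10, 109)),
                    scan_config(min_run = 2L, min_span_bp = 0L))
  far <- find_runs(make_mm(rep("G>A", 2), c(10, 110)),
                   scan_config(min_run = 2L, min_span_bp = 0L))
  expect_equal(nrow(apply_span_filter(near, cfg)), 0L)
  expect_equal(nrow(apply_span_filter(far, cfg)), 1L)
  once <- apply_span_filter(rbind(near, far), cfg)
  expect_equal(apply_span_filter(once, cfg), once)
})

test_that("motif filter keeps uniform 3-mers and drops N contexts", {
  cfg <- scan_config(min_run = 3L, min_span_bp = 0L)
  base <- find_runs(make_mm(rep("G>A", 3), c(10, 60, 150),
                            trace_motif = "AAA", ref_motif = "AGA"), cfg)
  expect_equal(nrow(apply_motif_filter(base, cfg)), 1L)

  mixed <- base
  mixed$members[[1]]$trace_motif <- c("AAA", "AAA", "AAG")
  expect_equal(nrow(apply_motif_filter(mixed, cfg)), 0L)

  withn <- base
  withn$members[[1]]$trace_motif <- c("AAA", "ANA", "AAA")
  expect_equal(nrow(apply_motif_filter(withn, cfg)), 0L)

  ## a read-edge mismatch has no full 3-mer and counts as N context
  edge <- find_runs(make_mm(rep("G>A", 3), c(0, 60, 150),
                            trace_motif = c("NGA", "AAA", "AAA"),
                            ref_motif = "AGA"), cfg)
  expect_equal(nrow(apply_motif_filter(edge, cfg)), 0L)
})
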
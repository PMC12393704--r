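# Breakpoint clustering, frequency estimation and full-length tests.

test_that("breakpoint clustering merges within tolerance, modal interval", {
  ev <- data.frame(
    read_id = sprintf("r%d", 1:6),
    start = c(rep(808L, 5L), 809L),
    end = rep(2560L, 6L)
  )
  ids <- cluster_breakpoints(ev, tolerance = 3L)
  expect_equal(nrow(ids), 1L)
  expect_equal(c(ids$start, ids$end, ids$support), c(808L, 2560L, 6L))

  ev2 <- data.frame(read_id = c("a", "b"), start = c(500L, 1500L),
                    end = c(1000L, 2000L))
  expect_equal(nrow(cluster_breakpoints(ev2, 3L)), 2L)

  ev3 <- data.frame(read_id = sprintf("r%d", 1:4), start = 100L, end = 300L)
  ids3 <- cluster_breakpoints(ev3, tolerance = 0L)
  expect_equal(ids3$support, 4L)
})

test_that("baseline coverage excludes deleted regions and trimmed ends", {
  # depth 40 outside [1000,1500], depth 4 inside
  aln <- rbind(
    aln_df(rep(1L, 4L), "2907M"),
    aln_df(rep(1L, 36L), "999M501D1407M")
  )
  prof <- coverage_profile(aln, 2907L)
  ids <- data.frame(start = 1000L, end = 1500L)
  expect_equal(mean_coverage_outside_ids(prof, ids, end_trim = 50L), 40)

  flat <- uniform_profile(40L, 2907L)
  expect_equal(mean_coverage_outside_ids(flat, ids), 40)

  # zero-coverage leading 50 bp removed by the trim
  aln2 <- aln_df(rep(51L, 40L), "2857M")
  expect_equal(
    mean_coverage_outside_ids(coverage_profile(aln2, 2907L), NULL, 50L),
    40)
  expect_error(
    mean_coverage_outside_ids(flat, data.frame(start = 1L, end = 2907L)),
    "no positions")
})

test_that("frequencies are support/baseline, clamped, singletons dropped", {
  ids <- data.frame(start = c(100L, 400L, 900L), end = c(300L, 600L, 1200L),
                    support = c(12L, 60L, 1L))
  out <- id_frequency(ids, baseline = 48)
  expect_equal(nrow(out), 2L)   # singleton removed
  expect_equal(out$frequency, c(0.25, 1))
  expect_error(id_frequency(ids, 0), "positive")
})

test_that("frequency filter keeps >= 0.05 and preserves order", {
  ids <- data.frame(start = 1:3, end = 4:6,
                    frequency = c(0.05, 0.27, 0.049))
  kept <- filter_ids(ids)
  expect_equal(kept$frequency, c(0.05, 0.27))
  expect_equal(nrow(filter_ids(ids[0, ])), 0L)
  expect_equal(filter_ids(ids, 0), ids)
})

test_that("full-length frequency is min mean depth over baseline", {
  flat <- uniform_profile(40L, 2907L)
  est <- full_length_frequency(list(flat), baseline = 40)
  expect_equal(est$frequency, 1)

  hole <- coverage_profile(aln_df(rep(1L, 40L), "999M501D1407M"), 2907L)
  expect_equal(full_length_frequency(list(hole), 40)$frequency, 0)
})

test_that("zero-coverage regions rule out full-length insertions", {
  hole <- coverage_profile(aln_df(rep(1L, 3L), "999M501D1407M"), 2907L)
  res <- full_length_possible(hole)
  expect_false(res$possible)
  expect_equal(res$zero_intervals, data.frame(start = 1000L, end = 1500L))

  flat <- uniform_profile(2L, 2907L)
  expect_true(full_length_possible(flat)$possible)

  # two deletions, both reported
  two <- coverage_profile(
    aln_df(rep(1L, 3L), "299M601D699M601D707M"), 2907L)
  res2 <- full_length_possible(two)
  expect_false(res2$possible)
  expect_equal(nrow(res2$zero_intervals), 2L)
})

test_that("deletion landscape averages frequencies of spanning deletions", {
  ids <- data.frame(start = c(500L, 1000L), end = c(1500L, 2000L),
                    frequency = c(0.2, 0.4))
  lsc <- deletion_landscape(ids, 2907L)
  expect_equal(lsc[1200L], 0.3)
  expect_equal(lsc[100L], 0)
  expect_equal(lsc[1800L], 0.4)
  expect_true(all(lsc <= max(ids$frequency)))
  expect_true(all(lsc[-(500:2000)] == 0))
})

test_that("the deletion pipeline recovers simulated intervals/frequencies", {
  scg <- make_scg()
  truth_f <- c(fl = 0.39, a = 0.10, kp = 0.27, tr = 0.24)
  pool <- haplotype_pool(list(
    deletion_variant("fl", data.frame(start = integer(), end = integer()),
                     CONS, truth_f[["fl"]]),
    deletion_variant("a", data.frame(start = 600L, end = 2200L), CONS,
                     truth_f[["a"]]),
    deletion_variant("kp", data.frame(start = 808L, end = 2560L), CONS,
                     truth_f[["kp"]]),
    deletion_variant("tr", data.frame(start = 200L, end = 1500L), CONS,
                     truth_f[["tr"]])
  ), haploid_copy_number = 8, n_individuals = 60L)
  sim <- simulate_pool_reads(pool, CONS, scg, coverage = 50, seed = 17L)
  aln <- read_alignments(sim$sam, CONS$name)
  prof <- coverage_profile(aln, CONS$length)
  ids <- cluster_breakpoints(extract_split_reads(aln))
  expect_equal(ids[, c("start", "end")],
               data.frame(start = c(200L, 600L, 808L),
                          end = c(1500L, 2200L, 2560L)))
  baseline <- mean_coverage_outside_ids(prof, ids)
  ids <- filter_ids(id_frequency(ids, baseline))
  realized <- setNames(sim$truth$frequency, sim$truth$variant_id)
  expect_true(all(abs(ids$frequency - realized[c("tr", "a", "kp")]) <=
                    0.05))
  # frequency mass accounting: kept deletions + full length stay <= 1 + eps
  fl_est <- full_length_frequency(list(prof), baseline)
  expect_true(abs(fl_est$frequency - realized[["fl"]]) <= 0.06)
  expect_lt(sum(ids$frequency) + fl_est$frequency, 1 + 0.1)
})
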
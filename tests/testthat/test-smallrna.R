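# Small-RNA class spectra, 1U bias and ping-pong/phasing signatures.

test_that("class filters apply the piRNA/siRNA length windows", {
  reads <- sr_df(100L, "+", c(21L, 26L, 29L, 30L))
  expect_equal(filter_by_class(reads, "piRNA")$length, c(26L, 29L))
  expect_equal(filter_by_class(reads, "siRNA")$length, 21L)
  expect_equal(nrow(filter_by_class(reads[0, ], "piRNA")), 0L)
})

test_that("length histogram and 1U bias are simple tallies", {
  reads <- sr_df(100L, "+", c(21L, 21L, 26L))
  h <- length_histogram(reads)
  expect_equal(unname(h[c("21", "26")]), c(2L, 1L))

  ten <- sr_df(1:10, "+", 26L,
               first_base = c(rep("U", 8L), "A", "G"))
  expect_equal(first_base_bias(ten), 0.8)
  expect_error(first_base_bias(ten[0, ]), "no reads")
})

test_that("position distribution splits strands and conserves reads", {
  reads <- sr_df(c(100L, 100L, 250L), c("+", "+", "-"), 26L)
  pd <- position_distribution(reads, 300L)
  expect_equal(pd$sense[100L], 2L)
  expect_equal(pd$antisense[250L], 1L)
  expect_equal(sum(pd$sense) + sum(pd$antisense), nrow(reads))
})

test_that("ping-pong distance follows the 5' overlap geometry", {
  pair <- sr_df(c(100L, 109L), c("+", "-"), 26L)
  sig <- ping_pong_signature(pair)
  expect_equal(unname(sig$distance_frequency["10"]), 1)
  expect_equal(sig$pair_count, 1)

  same <- sr_df(c(100L, 150L), "+", 26L)
  expect_equal(ping_pong_signature(same)$pair_count, 0L)
})

test_that("smallrna ingest orients 5' ends and first bases by strand", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6", "@SQ\tSN:ref\tLN:500",
    # plus read 5' at 100, first base T -> U
    paste0("p1\t0\tref\t100\t60\t5M\t*\t0\t0\tTACGA\t*"),
    # minus read spanning 200..204: 5' end at 204, read first base =
    # complement of last SEQ char (G -> C)
    paste0("m1\t16\tref\t200\t60\t5M\t*\t0\t0\tACGTG\t*")
  ), sam)
  reads <- smallrna_reads(read_alignments(sam, "ref"))
  expect_equal(nrow(reads), 0L)   # 5 nt reads fall outside 18-35 ingest

  writeLines(c(
    "@HD\tVN:1.6", "@SQ\tSN:ref\tLN:500",
    sprintf("p1\t0\tref\t100\t60\t26M\t*\t0\t0\t%s\t*",
            paste0("T", strrep("A", 25L))),
    sprintf("m1\t16\tref\t200\t60\t26M\t*\t0\t0\t%s\t*",
            paste0(strrep("C", 25L), "A"))
  ), sam)
  reads <- smallrna_reads(read_alignments(sam, "ref"))
  expect_equal(reads$pos5, c(100L, 225L))
  expect_equal(reads$first_base, c("U", "U"))
})

test_that("signatures are invariant under strand mirroring", {
  L <- CONS$length
  spec <- smallrna_sim_spec(n_pairs = 1500L)
  sim <- simulate_small_rnas(spec, CONS, "phased", seed = 9L)
  reads <- filter_by_class(
    smallrna_reads(read_alignments(sim$sam, CONS$name)), "piRNA")
  mirrored <- reads
  mirrored$strand <- ifelse(reads$strand == "+", "-", "+")
  mirrored$pos5 <- L + 1L - reads$pos5

  s1 <- ping_pong_signature(reads)
  s2 <- ping_pong_signature(mirrored)
  expect_equal(s1$distance_frequency, s2$distance_frequency)
  expect_equal(s1$pair_count, s2$pair_count)

  p1 <- phasing_signature(reads)
  p2 <- phasing_signature(mirrored)
  expect_equal(p1$distance_frequency, p2$distance_frequency)
})

test_that("structured pools show their signature, uniform pools are flat", {
  spec <- smallrna_sim_spec(n_pairs = 5000L)
  pp <- simulate_small_rnas(spec, CONS, "pingpong", seed = 3L)
  pir <- filter_by_class(
    smallrna_reads(read_alignments(pp$sam, CONS$name)), "piRNA")
  sig <- ping_pong_signature(pir)
  expect_equal(names(which.max(sig$distance_frequency)), "10")
  expect_gt(sig$z10, 5)

  # unpaired 21 nt pool: no ping-pong structure among its few piRNA-length
  # reads, and a flat signature on uniform random piRNA positions
  set.seed(31)
  unif <- sr_df(sample.int(2800L, 10000L, replace = TRUE),
                sample(c("+", "-"), 10000L, replace = TRUE),
                sample(23:29, 10000L, replace = TRUE))
  flat <- ping_pong_signature(unif)
  expect_lt(max(flat$distance_frequency),
            2 * mean(flat$distance_frequency))
  expect_lt(abs(flat$z10), 5)
})

test_that("phased pools put the modal 3'-to-5' distance at 1 nt", {
  spec <- smallrna_sim_spec(n_pairs = 4000L)
  ph <- simulate_small_rnas(spec, CONS, "phased", seed = 4L)
  pir <- filter_by_class(
    smallrna_reads(read_alignments(ph$sam, CONS$name)), "piRNA")
  psig <- phasing_signature(pir)
  expect_equal(names(which.max(psig$distance_frequency)), "1")
})

test_that("siRNA mode is 21 nt dominated with a weaker U bias", {
  si <- simulate_small_rnas(smallrna_sim_spec(n_pairs = 6000L), CONS,
                            "sirna", seed = 5L)
  reads <- smallrna_reads(read_alignments(si$sam, CONS$name))
  h <- length_histogram(reads)
  expect_equal(names(which.max(h)), "21")
  expect_lt(first_base_bias(reads), 0.7)
  # initiator bias in ping-pong pools is the configured 0.85
  pp <- simulate_small_rnas(smallrna_sim_spec(n_pairs = 4000L), CONS,
                            "pingpong", seed = 6L)
  aln <- read_alignments(pp$sam, CONS$name)
  # initiators carry the first block of read names
  init <- smallrna_reads(aln[aln$read_id %in% sprintf("sr_%06d", 1:4000), ])
  expect_lt(abs(first_base_bias(init) - 0.85), 0.03)
})
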
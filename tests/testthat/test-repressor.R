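# Variant reconstruction, germline CDS assembly, ORF-defect scanning and
# repressor classification.

test_that("variant reconstruction removes deleted intervals in order", {
  kp <- reconstruct_variant_sequence(CONS,
                                     data.frame(start = 808L, end = 2560L))
  expect_equal(nchar(kp), 2907L - 1753L)

  expect_equal(reconstruct_variant_sequence(
    CONS, data.frame(start = integer(), end = integer())), CONS$sequence)

  toy <- te_consensus("toy", paste0(rep("ACGTT", 20L), collapse = ""))
  two <- reconstruct_variant_sequence(
    toy, data.frame(start = c(10L, 30L), end = c(19L, 39L)))
  expect_equal(nchar(two), 80L)
  chars <- strsplit(toy$sequence, "")[[1L]]
  expect_equal(two, paste0(chars[c(1:9, 20:29, 40:100)], collapse = ""))

  expect_error(reconstruct_variant_sequence(
    CONS, data.frame(start = c(100L, 150L), end = c(200L, 250L))),
    "overlap")
})

test_that("germline CDS maps annotation through deletions", {
  orf2 <- feature(ANN, "ORF2")
  orf3 <- feature(ANN, "ORF3")
  # deleting ORF2+ORF3 leaves ORF0 + ORF1 in the message
  v <- deletion_variant("d23", data.frame(start = orf2$start,
                                          end = orf3$end), CONS)
  cds <- germline_cds(v, ANN, CONS)
  orf0 <- feature(ANN, "ORF0")
  orf1 <- feature(ANN, "ORF1")
  expect_equal(nchar(cds),
               (orf0$end - orf0$start + 1L) + (orf1$end - orf1$start + 1L))

  # a deletion of length not divisible by 3 inside ORF2 shifts the frame
  v2 <- deletion_variant("fs", data.frame(start = orf2$start + 30L,
                                          end = orf2$start + 59L + 1L),
                         CONS)
  cds2 <- germline_cds(v2, ANN, CONS)
  expect_true(any(attr(cds2, "shifted")))

  # same-length in-frame deletion does not
  v3 <- deletion_variant("if", data.frame(start = orf2$start + 30L,
                                          end = orf2$start + 59L), CONS)
  expect_false(any(attr(germline_cds(v3, ANN, CONS), "shifted")))
})

test_that("destroying a splice site retains the intron in the message", {
  iv2 <- feature(ANN, "IVS2")
  # clip the donor (first bases of IVS2) without touching coding sequence
  v <- deletion_variant("donor", data.frame(start = iv2$start,
                                            end = iv2$start + 3L), CONS)
  cds <- germline_cds(v, ANN, CONS)
  retained <- (iv2$end - iv2$start + 1L) - 4L
  expect_equal(nchar(cds), REF_CDS_LEN + retained)
  expect_true(length(attr(cds, "junctions")) > 0L)
})

test_that("ORF-defect scanning matches a brute-force translation oracle", {
  # toy element: 300 bp, entirely coding, stop-free with terminal TAA
  set.seed(300)
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1L, paste0,
                  collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  ref <- paste0("ATG", paste0(sample(sense, 98L, replace = TRUE),
                              collapse = ""), "TAA")
  n <- nchar(ref)

  oracle <- function(s, e) {
    del_len <- e - s + 1L
    cds <- paste0(substr(ref, 1L, s - 1L), substr(ref, e + 1L, n))
    m <- nchar(cds)
    if (m == 0L) return("deleted")
    shifted <- del_len %% 3L != 0L
    starts <- seq.int(1L, m - 2L, by = 3L)
    tri <- substring(cds, starts, starts + 2L)
    internal <- starts[tri %in% c("TAA", "TAG", "TGA") & starts + 2L < m]
    first_stop <- if (length(internal) > 0L) internal[1L] else NA_integer_
    junction <- min(s, m)   # first base after the deletion, in CDS coords
    if (shifted && (is.na(first_stop) || junction <= first_stop)) {
      return("frameshift")
    }
    if (!is.na(first_stop)) return("premature_stop")
    "deleted"
  }

  for (s in seq(4L, n - 6L, by = 7L)) {
    for (e in seq(s, n - 3L, by = 7L)) {
      cds <- paste0(substr(ref, 1L, s - 1L), substr(ref, e + 1L, n))
      got <- scan_orf_defects(cds, n, junctions = min(s, nchar(cds)),
                              shifted = (e - s + 1L) %% 3L != 0L)
      expect_equal(got$transposase_status, oracle(s, e),
                   label = sprintf("deletion [%d,%d]", s, e))
    }
  }
})

test_that("an in-frame deletion forging a stop at the junction is caught", {
  orf2 <- feature(ANN, "ORF2")
  chars <- strsplit(CONS$sequence, "")[[1L]]
  ref_pos <- pinvade:::.germline_positions(ANN)
  # brute-force search for an in-frame deletion inside ORF2 whose junction
  # codon reads TAA/TAG/TGA
  found <- NULL
  for (s in seq(orf2$start + 12L, orf2$start + 400L)) {
    cds_idx <- match(s, ref_pos)
    if (is.na(cds_idx)) next
    phase <- (cds_idx - 1L) %% 3L
    for (len in c(30L, 60L, 90L)) {
      e <- s + len - 1L
      if (e > orf2$end - 12L) next
      v <- deletion_variant("probe", data.frame(start = s, end = e), CONS)
      cds <- germline_cds(v, ANN, CONS)
      cstart <- cds_idx - phase
      junction_codon <- substr(cds, cstart, cstart + 2L)
      if (junction_codon %in% c("TAA", "TAG", "TGA")) {
        found <- c(s, e)
        break
      }
    }
    if (!is.null(found)) break
  }
  expect_false(is.null(found))
  v <- deletion_variant("stopmaker",
                        data.frame(start = found[1L], end = found[2L]), CONS)
  scan <- scan_orf_defects(germline_cds(v, ANN, CONS), REF_CDS_LEN)
  expect_equal(scan$transposase_status, "premature_stop")
})

test_that("classification follows the repressor criteria", {
  fl <- classify_variant(
    deletion_variant("fl", data.frame(start = integer(), end = integer()),
                     CONS, 0.5), ANN, CONS)
  expect_equal(fl$klass, "autonomous_full_length")
  expect_equal(fl$transposase_status, "intact")

  orf2 <- feature(ANN, "ORF2")
  orf3 <- feature(ANN, "ORF3")
  rep_call <- classify_variant(
    deletion_variant("kp", data.frame(start = orf2$start + 10L,
                                      end = orf3$end - 10L), CONS, 0.27),
    ANN, CONS)
  expect_false(rep_call$transposase_status == "intact")
  expect_equal(rep_call$dbd_status, "intact")
  expect_equal(rep_call$klass, "putative_repressor")

  dbd <- feature(ANN, "DNA_binding_domain")
  amb <- classify_variant(
    deletion_variant("tr", data.frame(start = dbd$end - 20L, end = 1500L),
                     CONS, 0.24), ANN, CONS)
  expect_equal(amb$dbd_status, "truncated")
  expect_equal(amb$klass, "ambiguous_nonautonomous")

  gone <- classify_variant(
    deletion_variant("nodbd", data.frame(start = dbd$start - 20L,
                                         end = dbd$end + 20L), CONS, 0.1),
    ANN, CONS)
  expect_equal(gone$dbd_status, "absent")
  expect_equal(gone$klass, "other_nonautonomous")

  # a frameshift upstream of the domain truncates the encoded domain even
  # when the interval itself is untouched
  orf0 <- feature(ANN, "ORF0")
  fs <- classify_variant(
    deletion_variant("fs0", data.frame(start = orf0$start + 6L,
                                       end = orf0$start + 19L), CONS,
                     0.1), ANN, CONS)
  expect_equal(fs$dbd_status, "truncated")
})

test_that("damage is monotone: more deletion never restores autonomy", {
  set.seed(77)
  for (i in 1:10) {
    s <- sample(200:2200, 1L)
    e <- s + sample(50:500, 1L)
    v1 <- classify_variant(
      deletion_variant("v1", data.frame(start = s, end = e), CONS, 0.1),
      ANN, CONS)
    e2 <- min(e + sample(30:300, 1L), 2850L)
    v2 <- classify_variant(
      deletion_variant("v2", data.frame(start = s, end = e2), CONS, 0.1),
      ANN, CONS)
    if (v1$klass != "autonomous_full_length") {
      expect_false(v2$klass == "autonomous_full_length")
    }
  }
})

test_that("classification is order-invariant and class sums are exact", {
  orf2 <- feature(ANN, "ORF2")
  calls <- list(
    classify_variant(deletion_variant(
      "a", data.frame(start = 808L, end = 2560L), CONS, 0.27), ANN, CONS),
    classify_variant(deletion_variant(
      "b", data.frame(start = orf2$start + 1L, end = orf2$start + 100L),
      CONS, 0.10), ANN, CONS),
    classify_variant(deletion_variant(
      "c", data.frame(start = 200L, end = 1500L), CONS, 0.24), ANN, CONS)
  )
  s1 <- summarize_classes(calls)
  s2 <- summarize_classes(rev(calls))
  expect_equal(s1$class_percent, s2$class_percent)
  expect_equal(unname(s1$repressor_range), c(37, 61))

  single <- summarize_classes(list(classify_variant(deletion_variant(
    "r3", data.frame(start = 808L, end = 2560L), CONS, 0.05), ANN, CONS)))
  expect_equal(unname(single$repressor_range), c(5, 5))

  none <- summarize_classes(list())
  expect_true(all(none$class_percent == 0))
})
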
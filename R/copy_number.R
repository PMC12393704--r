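# Copy-number estimation by normalisation to single-copy genes.

#' Mean coverage of the single-copy genes
#'
#' Averages the per-gene mean depths, weighting each gene equally. This is
#' the normaliser turning raw TE depth into copies per haploid genome: a
#' single-copy gene is present exactly once per haploid genome, so its depth
#' measures the sequencing effort per haploid genome.
#'
#' @param profiles List of [coverage_profile()] objects, one per single-copy
#'   gene.
#' @return Mean single-copy-gene coverage (reads).
#' @export
scg_mean_coverage <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  means <- vapply(profiles, function(p) mean(p$depth), numeric(1L))
  m <- mean(means)
  if (m <= 0) {
    stop("single-copy genes have zero coverage; normalisation impossible",
         call. = FALSE)
  }
  m
}

#' Estimate TE copies per haploid genome
#'
#' The estimator divides the mean depth over the full consensus by the mean
#' single-copy-gene coverage: a TE at 50x coverage with single-copy genes at
#' 5x implies 10 copies per haploid genome. The mean is taken over all
#' consensus positions, deleted regions included, so the estimate reflects
#' sequence dosage rather than insertion count when internal deletions
#' segregate.
#'
#' @param te_profile A [coverage_profile()] over the full consensus.
#' @param scg_cov Mean single-copy-gene coverage, from [scg_mean_coverage()].
#' @return A list of class `copy_number_estimate`: `sample_id`,
#'   `copies_per_haploid`, `scg_mean_coverage`, `te_mean_coverage`.
#' @export
estimate_copy_number <- function(te_profile, scg_cov) {
  if (scg_cov <= 0) {
    stop("single-copy-gene coverage must be positive", call. = FALSE)
  }
  te_mean <- mean(te_profile$depth)
  structure(
    list(sample_id = te_profile$sample_id,
         copies_per_haploid = te_mean / scg_cov,
         scg_mean_coverage = scg_cov,
         te_mean_coverage = te_mean),
    class = "copy_number_estimate"
  )
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat("<copy_number_estimate>", round(x$copies_per_haploid, 2),
      "copies/haploid (TE", round(x$te_mean_coverage, 2), "x / SCG",
      round(x$scg_mean_coverage, 2), "x)\n")
  invisible(x)
}

#' Normalise a coverage profile to single-copy-gene coverage
#'
#' Element-wise division of depth by the single-copy-gene coverage; the mean
#' of the normalised profile equals the copy-number estimate.
#'
#' @inheritParams estimate_copy_number
#' @return A `normalized_profile` object: list with `reference_name`,
#'   `norm_depth`, `sample_id`.
#' @export
normalize_profile <- function(te_profile, scg_cov) {
  if (scg_cov <= 0) {
    stop("single-copy-gene coverage must be positive", call. = FALSE)
  }
  structure(
    list(reference_name = te_profile$reference_name,
         norm_depth = te_profile$depth / scg_cov,
         sample_id = te_profile$sample_id),
    class = "normalized_profile"
  )
}
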
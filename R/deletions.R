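# Internal-deletion calling: breakpoint clustering, frequency estimation,
# frequency filtering, full-length tests and the deletion landscape.

#' Cluster split-read evidence into internal deletions
#'
#' Evidence records whose start and end coordinates each differ by at most
#' `tolerance` bp are merged into one internal deletion. The merged interval
#' takes the support-weighted modal coordinates (ties broken towards the
#' smallest start and largest end); support is the number of merged reads.
#'
#' @param evidence Data.frame from [extract_split_reads()].
#' @param tolerance Maximum per-breakpoint discrepancy in bp (default 3).
#' @return Data.frame of internal deletions, sorted by start: `start`, `end`,
#'   `support` (frequency unset).
#' @export
cluster_breakpoints <- function(evidence, tolerance = 3L) {
  stopifnot(tolerance >= 0L)
  empty <- data.frame(start = integer(), end = integer(),
                      support = integer())
  if (is.null(evidence) || nrow(evidence) == 0L) {
    return(empty)
  }
  key <- paste(evidence$start, evidence$end)
  tab <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- do.call(rbind, strsplit(tab$key, " "))
  uniq <- data.frame(start = as.integer(parts[, 1L]),
                     end = as.integer(parts[, 2L]),
                     n = tab$Freq)
  # modal-first greedy assignment: highest support seeds a cluster,
  # ties -> smallest start, then largest end
  uniq <- uniq[order(-uniq$n, uniq$start, -uniq$end), , drop = FALSE]
  out <- empty
  while (nrow(uniq) > 0L) {
    seed <- uniq[1L, ]
    member <- abs(uniq$start - seed$start) <= tolerance &
      abs(uniq$end - seed$end) <= tolerance
    out <- rbind(out, data.frame(start = seed$start, end = seed$end,
                                 support = sum(uniq$n[member])))
    uniq <- uniq[!member, , drop = FALSE]
  }
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean coverage outside internally deleted regions
#'
#' The baseline used to convert split-read counts into frequencies: the mean
#' depth over consensus positions not contained in any internal deletion,
#' excluding `end_trim` bp at either end of the element where coverage is
#' systematically lower.
#'
#' @param profile A [coverage_profile()] over the full consensus.
#' @param ids Data.frame of internal deletions (`start`, `end`); may be empty.
#' @param end_trim Bases trimmed from each end (default 50).
#' @return Mean depth (reads) over the qualifying positions.
#' @export
mean_coverage_outside_ids <- function(profile, ids = NULL, end_trim = 50L) {
  stopifnot(end_trim >= 0L)
  L <- length(profile$depth)
  keep <- rep(TRUE, L)
  if (end_trim > 0L) {
    keep[c(seq_len(min(end_trim, L)),
           seq.int(max(1L, L - end_trim + 1L), L))] <- FALSE
  }
  if (!is.null(ids) && nrow(ids) > 0L) {
    keep[.interval_mask(ids, L)] <- FALSE
  }
  if (!any(keep)) {
    stop("no positions left outside deletions after end trimming",
         call. = FALSE)
  }
  mean(profile$depth[keep])
}

#' Estimate internal-deletion frequencies
#'
#' The population frequency of a deletion is the number of split reads
#' supporting it divided by the baseline coverage outside deleted regions,
#' clamped to [0, 1]. Deletions with fewer than `min_support` reads are
#' dropped as singleton artefacts before estimation.
#'
#' @param ids Data.frame from [cluster_breakpoints()].
#' @param baseline Mean coverage from [mean_coverage_outside_ids()].
#' @param min_support Minimum split-read support (default 2).
#' @return `ids` with a `frequency` column added.
#' @export
id_frequency <- function(ids, baseline, min_support = 2L) {
  if (baseline <= 0) {
    stop("baseline coverage must be positive", call. = FALSE)
  }
  ids <- ids[ids$support >= min_support, , drop = FALSE]
  ids$frequency <- pmin(1, ids$support / baseline)
  rownames(ids) <- NULL
  ids
}

#' Filter internal deletions by frequency
#'
#' Keeps deletions at or above the frequency threshold (default 0.05),
#' preserving order. Low-frequency deletions are dominated by sampling noise
#' in pooled data.
#'
#' @param ids Data.frame with a `frequency` column.
#' @param min_frequency Threshold (default 0.05); deletions with
#'   `frequency >= min_frequency` are kept.
#' @return Filtered data.frame.
#' @export
filter_ids <- function(ids, min_frequency = 0.05) {
  if (nrow(ids) == 0L) {
    return(ids)
  }
  out <- ids[ids$frequency >= min_frequency, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate the full-length frequency of a replicate
#'
#' The frequency of intact full-length copies is bounded by the depth at the
#' least-covered position: positions inside any internal deletion receive no
#' reads from the deleted copies, so the minimum of the cross-individual
#' mean depth, divided by the baseline coverage, estimates the fraction of
#' copies that are full length. End positions are trimmed as for the
#' baseline.
#'
#' @param profiles List of [coverage_profile()] objects (individuals of a
#'   replicate; raw depth).
#' @param baseline Mean coverage from [mean_coverage_outside_ids()].
#' @param end_trim Bases trimmed from each end (default 50).
#' @param sample_id Replicate label.
#' @return List of class `full_length_estimate`: `sample_id`, `frequency`.
#' @export
full_length_frequency <- function(profiles, baseline, end_trim = 50L,
                                  sample_id = NA_character_) {
  stopifnot(length(profiles) >= 1L)
  if (baseline <= 0) {
    stop("baseline coverage must be positive", call. = FALSE)
  }
  depth <- rowMeans(vapply(profiles, function(p) as.numeric(p$depth),
                           numeric(length(profiles[[1L]]$depth))))
  L <- length(depth)
  keep <- seq.int(1L + end_trim, L - end_trim)
  freq <- min(depth[keep]) / baseline
  structure(list(sample_id = sample_id,
                 frequency = max(0, min(1, freq))),
            class = "full_length_estimate")
}

#' Can a sample contain a full-length insertion?
#'
#' If any consensus position has zero coverage, the sample cannot carry a
#' single full-length copy. The converse does not hold: non-overlapping
#' deletions in different insertions can tile the element with coverage, so
#' a `TRUE` result is conservative evidence only.
#'
#' @param profile A [coverage_profile()] over the full consensus.
#' @param end_trim Bases at either end excluded from the test (default 0).
#' @return List with `possible` (logical) and `zero_intervals` (data.frame of
#'   maximal zero-depth intervals, empty when `possible`).
#' @export
full_length_possible <- function(profile, end_trim = 0L) {
  L <- length(profile$depth)
  inspect <- seq.int(1L + end_trim, L - end_trim)
  zero <- rep(FALSE, L)
  zero[inspect] <- profile$depth[inspect] == 0L
  runs <- .runs_of(zero)
  list(possible = nrow(runs) == 0L, zero_intervals = runs)
}

#' Per-site deletion landscape
#'
#' For each consensus position, the mean frequency of all internal deletions
#' whose interval contains the position (0 where none). High values flag
#' regions whose loss is, on average, favourable for a deletion reaching
#' high frequency — a fitness landscape of internal deletions.
#'
#' @param ids Data.frame with `start`, `end`, `frequency`.
#' @param length Consensus length in bp.
#' @return Numeric vector of length `length`.
#' @export
deletion_landscape <- function(ids, length) {
  total <- numeric(length)
  n <- integer(length)
  if (nrow(ids) > 0L) {
    for (i in seq_len(nrow(ids))) {
      span <- ids$start[i]:ids$end[i]
      total[span] <- total[span] + ids$frequency[i]
      n[span] <- n[span] + 1L
    }
  }
  ifelse(n > 0L, total / pmax(n, 1L), 0)
}
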
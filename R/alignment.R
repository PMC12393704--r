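# SAM ingest, per-position coverage and split-read extraction.

#' Read alignments from a SAM file
#'
#' Streams the mapped, non-secondary records on one reference out of a SAM
#' file. Supplementary alignments are retained and flagged, so that split
#' alignments of one read can later be paired into deletion evidence.
#'
#' @param sam_path Path to a SAM file (text).
#' @param reference_name Reference to extract; must be present in the header.
#' @return A data.frame with one row per alignment: `read_id`,
#'   `reference_name`, `start`, `end`, `strand`, `cigar`, `mapq`, `seq`,
#'   `is_supplementary`.
#' @export
read_alignments <- function(sam_path, reference_name) {
  if (!file.exists(sam_path)) {
    stop("SAM file not found: ", sam_path, call. = FALSE)
  }
  bam <- Rsamtools::asBam(sam_path,
                          destination = tempfile(),
                          overwrite = TRUE, indexDestination = FALSE)
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (!reference_name %in% names(hdr)) {
    stop("reference '", reference_name, "' not present in SAM header",
         call. = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("qname", "flag", "mapq", "seq")
  )
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  keep <- as.character(GenomicAlignments::seqnames(ga)) == reference_name
  ga <- ga[keep]
  m <- S4Vectors::mcols(ga)
  data.frame(
    read_id = m$qname,
    reference_name = reference_name,
    start = GenomicAlignments::start(ga),
    end = GenomicAlignments::end(ga),
    strand = as.character(GenomicAlignments::strand(ga)),
    cigar = GenomicAlignments::cigar(ga),
    mapq = m$mapq,
    seq = as.character(m$seq),
    is_supplementary = bitwAnd(m$flag, 2048L) > 0L,
    stringsAsFactors = FALSE
  )
}

#' Per-position read depth over a reference
#'
#' Depth at position i counts the alignments whose CIGAR consumes reference
#' base i through an aligned operation (`M`, `=`, `X`). Deletion (`D`) and
#' skip (`N`) gaps do not add depth.
#'
#' @param alignments Data.frame as returned by [read_alignments()].
#' @param reference_length Length of the reference in bp.
#' @param sample_id Optional sample label carried along in reports.
#' @return A `coverage_profile` object: list with `reference_name`, `depth`
#'   (integer vector of length `reference_length`) and `sample_id`.
#' @export
coverage_profile <- function(alignments, reference_length,
                             sample_id = NA_character_) {
  ref <- if (nrow(alignments) > 0L) alignments$reference_name[1L] else NA
  if (nrow(alignments) == 0L) {
    return(structure(list(reference_name = ref,
                          depth = integer(reference_length),
                          sample_id = sample_id),
                     class = "coverage_profile"))
  }
  rng <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    alignments$cigar, pos = alignments$start, ops = c("M", "=", "X")
  )
  ir <- unlist(rng, use.names = FALSE)
  if (length(ir) > 0L && max(IRanges::end(ir)) > reference_length) {
    stop("alignment extends past reference length ", reference_length,
         call. = FALSE)
  }
  depth <- as.integer(IRanges::coverage(ir, width = reference_length))
  structure(list(reference_name = ref, depth = depth, sample_id = sample_id),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("<coverage_profile>", x$reference_name, "-", length(x$depth),
      "bp, mean depth", round(mean(x$depth), 2), "\n")
  invisible(x)
}

#' Extract split-read evidence of internal deletions
#'
#' Each within-read reference gap (CIGAR `D` or `N`) of at least `min_gap`
#' bp yields one evidence record with the skipped consensus interval. In
#' addition, primary/supplementary alignments of the same read on the same
#' strand whose aligned spans leave a reference gap of at least `min_gap`
#' yield one record for the skipped interval.
#'
#' @param alignments Data.frame as returned by [read_alignments()].
#' @param min_gap Minimum gap width in bp (default 20) separating internal
#'   deletions from small indel polymorphisms.
#' @return Data.frame with `read_id`, `start`, `end` (1-based closed deleted
#'   interval).
#' @export
extract_split_reads <- function(alignments, min_gap = 20L) {
  stopifnot(min_gap >= 1L)
  empty <- data.frame(read_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (nrow(alignments) == 0L) {
    return(empty)
  }
  rng <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    alignments$cigar, pos = alignments$start, ops = c("D", "N")
  )
  n_per <- lengths(rng)
  ir <- unlist(rng, use.names = FALSE)
  out <- data.frame(
    read_id = rep(alignments$read_id, n_per),
    start = IRanges::start(ir),
    end = IRanges::end(ir),
    stringsAsFactors = FALSE
  )
  out <- out[out$end - out$start + 1L >= min_gap, , drop = FALSE]

  # pair primary + supplementary spans of the same read/strand
  supp_ids <- unique(alignments$read_id[alignments$is_supplementary])
  for (id in supp_ids) {
    a <- alignments[alignments$read_id == id, , drop = FALSE]
    for (s in unique(a$strand)) {
      b <- a[a$strand == s, , drop = FALSE]
      if (nrow(b) < 2L) next
      b <- b[order(b$start), , drop = FALSE]
      gap_s <- b$end[-nrow(b)] + 1L
      gap_e <- b$start[-1L] - 1L
      ok <- (gap_e - gap_s + 1L) >= min_gap
      if (any(ok)) {
        out <- rbind(out, data.frame(read_id = id, start = gap_s[ok],
                                     end = gap_e[ok],
                                     stringsAsFactors = FALSE))
      }
    }
  }
  rownames(out) <- NULL
  out
}
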
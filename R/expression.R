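# RNA-seq based quantification: per-intron splicing and sense/antisense
# expression of the element.

# reference intervals of N gaps, one data.frame row per gap
.splice_gaps <- function(alignments) {
  rng <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    alignments$cigar, pos = alignments$start, ops = "N"
  )
  n_per <- lengths(rng)
  ir <- unlist(rng, use.names = FALSE)
  data.frame(row = rep(seq_len(nrow(alignments)), n_per),
             start = IRanges::start(ir), end = IRanges::end(ir))
}

#' Per-intron splicing levels
#'
#' A read supports splicing of an intron when its CIGAR contains an `N` gap
#' whose reference interval equals the annotated intron exactly. Levels are
#' reported as spliced reads per million mapped library reads (srpm).
#'
#' @param alignments RNA-seq alignments from [read_alignments()].
#' @param annotation Annotation data.frame with IVS1-IVS3 features.
#' @param library_size Total mapped reads in the library.
#' @return Data.frame `intron_id`, `spliced_read_count`, `srpm`.
#' @export
splicing_levels <- function(alignments, annotation, library_size) {
  if (library_size <= 0) {
    stop("library size must be positive", call. = FALSE)
  }
  gaps <- if (nrow(alignments) > 0L) .splice_gaps(alignments) else
    data.frame(row = integer(), start = integer(), end = integer())
  out <- data.frame(intron_id = character(), spliced_read_count = integer(),
                    srpm = numeric(), stringsAsFactors = FALSE)
  for (k in 1:3) {
    id <- paste0("IVS", k)
    iv <- feature(annotation, id)
    if (nrow(iv) != 1L) {
      stop("annotation must define ", id, call. = FALSE)
    }
    n <- sum(gaps$start == iv$start & gaps$end == iv$end)
    out <- rbind(out, data.frame(intron_id = id, spliced_read_count = n,
                                 srpm = n / (library_size / 1e6),
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Estimate the splicing rate of one intron
#'
#' Rate = spliced / (spliced + intron-retained junction reads), where a
#' retained junction read aligns continuously through the donor site (its
#' aligned bases cover both the last exonic base and the first intronic
#' base).
#'
#' @param alignments RNA-seq alignments from [read_alignments()].
#' @param intron One-row data.frame (`start`, `end`) of the intron.
#' @return Estimated rate in [0, 1], or `NA` without junction reads.
#' @export
splicing_rate <- function(alignments, intron) {
  if (nrow(alignments) == 0L) {
    return(NA_real_)
  }
  gaps <- .splice_gaps(alignments)
  spliced <- sum(gaps$start == intron$start & gaps$end == intron$end)
  rng <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    alignments$cigar, pos = alignments$start, ops = c("M", "=", "X")
  )
  retained <- sum(vapply(rng, function(ir) {
    any(IRanges::start(ir) <= intron$start - 1L &
          IRanges::end(ir) >= intron$start)
  }, logical(1L)))
  if (spliced + retained == 0L) {
    return(NA_real_)
  }
  spliced / (spliced + retained)
}

#' Sense/antisense expression of the element
#'
#' Reads per kilobase of element per million mapped library reads (rpkm),
#' split by alignment strand (sense = forward consensus strand).
#'
#' @param alignments RNA-seq alignments from [read_alignments()].
#' @param te_length Consensus length in bp.
#' @param library_size Total mapped reads in the library.
#' @param sample_id Optional sample label.
#' @return List of class `expression_estimate`: `sample_id`, `sense_rpkm`,
#'   `antisense_rpkm`, `total_rpkm`.
#' @export
te_expression <- function(alignments, te_length, library_size,
                          sample_id = NA_character_) {
  if (library_size <= 0) {
    stop("library size must be positive", call. = FALSE)
  }
  per_kb <- te_length / 1000
  per_m <- library_size / 1e6
  n_sense <- sum(alignments$strand == "+")
  n_anti <- sum(alignments$strand == "-")
  structure(
    list(sample_id = sample_id,
         sense_rpkm = n_sense / per_kb / per_m,
         antisense_rpkm = n_anti / per_kb / per_m,
         total_rpkm = (n_sense + n_anti) / per_kb / per_m),
    class = "expression_estimate"
  )
}
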
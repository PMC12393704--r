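# Full-length census rules for short-read samples and long-read assemblies.

#' Does a short-read sample contain a full-length insertion?
#'
#' A sample whose normalised coverage exceeds 1 over the whole element is
#' taken to carry at least one full-length insertion; any position at or
#' below 1 fails the rule. The `region` argument restricts the test to a
#' sub-interval (e.g. the central region, where abundant internal deletions
#' depress coverage most).
#'
#' @param profile A [normalize_profile()] result over the full consensus.
#' @param region Optional `c(start, end)` restriction.
#' @return Logical.
#' @export
shortread_has_full_length <- function(profile, region = NULL) {
  nd <- profile$norm_depth
  if (!is.null(region)) {
    nd <- nd[region[1L]:region[2L]]
  }
  min(nd) > 1
}

#' Minimum length of a full-length insertion
#'
#' An assembly insertion is considered full length when its aligned length
#' exceeds a fixed fraction of the consensus (default 80%, i.e. 2325 bp for
#' a 2907 bp element).
#'
#' @param consensus_length Consensus length in bp.
#' @param fraction Fraction of the consensus (default 0.8).
#' @return Threshold in bp: `floor(fraction * consensus_length)`.
#' @export
full_length_threshold <- function(consensus_length, fraction = 0.8) {
  as.integer(floor(fraction * consensus_length))
}

#' Parse a RepeatMasker .out annotation
#'
#' Reads the standard RepeatMasker `.out` column layout and returns the
#' hits matching the element, with consensus coordinates normalised so that
#' start <= end regardless of strand (`C` rows report repeat coordinates in
#' (left) end begin order).
#'
#' @param path Path to a RepeatMasker `.out` file.
#' @param te_name Repeat name to keep (default: keep all rows).
#' @return Data.frame of class `assembly_hits`: `contig`, `contig_start`,
#'   `contig_end`, `strand`, `repeat_name`, `cons_start`, `cons_end`,
#'   `aligned_length`.
#' @export
parse_repeatmasker_out <- function(path, te_name = NULL) {
  if (!file.exists(path)) {
    stop("RepeatMasker file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  # skip the two header lines + blank line if present
  body <- grep("^\\s*[0-9]", lines, value = FALSE)
  out <- data.frame(contig = character(), contig_start = integer(),
                    contig_end = integer(), strand = character(),
                    repeat_name = character(), cons_start = integer(),
                    cons_end = integer(), aligned_length = integer(),
                    stringsAsFactors = FALSE)
  for (i in body) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(f) < 14L) {
      stop("malformed RepeatMasker row at line ", i, call. = FALSE)
    }
    strand <- f[9L]
    if (!strand %in% c("+", "C")) {
      stop("malformed strand field at line ", i, call. = FALSE)
    }
    strip <- function(x) as.integer(gsub("[()]", "", x))
    if (strand == "+") {
      cs <- strip(f[12L]); ce <- strip(f[13L])
    } else {
      cs <- strip(f[14L]); ce <- strip(f[13L])  # C rows: (left) end begin
    }
    if (cs > ce) { tmp <- cs; cs <- ce; ce <- tmp }
    out <- rbind(out, data.frame(
      contig = f[5L], contig_start = as.integer(f[6L]),
      contig_end = as.integer(f[7L]),
      strand = if (strand == "C") "-" else "+",
      repeat_name = f[10L], cons_start = cs, cons_end = ce,
      aligned_length = ce - cs + 1L, stringsAsFactors = FALSE
    ))
  }
  if (!is.null(te_name)) {
    out <- out[out$repeat_name == te_name, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("assembly_hits", "data.frame")
  out
}

#' Census of element insertions in an assembly
#'
#' Hits on the same contig and strand within `merge_gap` bp of one another
#' and with compatible (ordered) consensus coordinates are merged into one
#' insertion, healing assembly-gap fragmentation. A merged insertion's
#' aligned length is the union length of its fragments' consensus
#' intervals (not the span, so an internally deleted copy reported as two
#' flanking fragments keeps its true aligned length); insertions whose
#' aligned length strictly exceeds the threshold are counted as full
#' length, the rest as internally deleted.
#'
#' @param hits Data.frame from [parse_repeatmasker_out()].
#' @param threshold Length threshold in bp, from [full_length_threshold()].
#' @param merge_gap Maximum contig gap between fragments of one insertion
#'   (default 100 bp).
#' @param sample_id Optional sample label.
#' @return List of class `census_result`: `sample_id`, `n_full_length`,
#'   `n_internally_deleted`, `has_full_length`, `insertions` (merged
#'   data.frame).
#' @export
census_assembly <- function(hits, threshold, merge_gap = 100L,
                            sample_id = NA_character_) {
  stopifnot(threshold >= 1L)
  merged <- data.frame(contig = character(), strand = character(),
                       contig_start = integer(), contig_end = integer(),
                       cons_start = integer(), cons_end = integer(),
                       aligned_length = integer(), stringsAsFactors = FALSE)
  union_len <- function(iv) {
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = iv$start, end = iv$end))))
  }
  if (nrow(hits) > 0L) {
    for (key in unique(paste(hits$contig, hits$strand))) {
      sub <- hits[paste(hits$contig, hits$strand) == key, , drop = FALSE]
      sub <- sub[order(sub$contig_start), , drop = FALSE]
      cur <- sub[1L, ]
      last <- cur
      frags <- data.frame(start = cur$cons_start, end = cur$cons_end)
      flush <- function(m, cur, frags) {
        rbind(m, data.frame(
          contig = cur$contig, strand = cur$strand,
          contig_start = cur$contig_start, contig_end = cur$contig_end,
          cons_start = min(frags$start), cons_end = max(frags$end),
          aligned_length = union_len(frags),
          stringsAsFactors = FALSE
        ))
      }
      if (nrow(sub) > 1L) {
        for (i in 2:nrow(sub)) {
          nxt <- sub[i, ]
          gap <- nxt$contig_start - cur$contig_end - 1L
          # along the contig, fragments of one insertion advance through
          # the consensus: forwards on "+", backwards on "-"
          ordered <- if (cur$strand == "+") {
            nxt$cons_start > last$cons_start && nxt$cons_end > last$cons_end
          } else {
            nxt$cons_start < last$cons_start && nxt$cons_end < last$cons_end
          }
          if (gap <= merge_gap && ordered) {
            cur$contig_end <- max(cur$contig_end, nxt$contig_end)
            frags <- rbind(frags, data.frame(start = nxt$cons_start,
                                             end = nxt$cons_end))
            last <- nxt
          } else {
            merged <- flush(merged, cur, frags)
            cur <- nxt
            last <- nxt
            frags <- data.frame(start = cur$cons_start,
                                end = cur$cons_end)
          }
        }
      }
      merged <- flush(merged, cur, frags)
    }
  }
  n_full <- sum(merged$aligned_length > threshold)
  structure(
    list(sample_id = sample_id,
         n_full_length = n_full,
         n_internally_deleted = nrow(merged) - n_full,
         has_full_length = n_full >= 1L,
         insertions = merged),
    class = "census_result"
  )
}
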
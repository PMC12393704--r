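# Small-RNA signatures: class spectra, 1U bias, positional distributions,
# ping-pong and phasing.

#' Build a small-RNA read table from alignments
#'
#' Converts alignment records into the small-RNA representation used by the
#' signature functions: the 5' end coordinate on the consensus forward
#' strand (for minus-strand reads this is the highest consensus coordinate
#' of the alignment), the strand, the read length and the 5'-most base in
#' RNA alphabet. Reads outside 18-35 nt are dropped at ingest.
#'
#' @param alignments Data.frame from [read_alignments()].
#' @return Data.frame with `pos5`, `strand`, `length`, `first_base`.
#' @export
smallrna_reads <- function(alignments) {
  if (nrow(alignments) == 0L) {
    return(data.frame(pos5 = integer(), strand = character(),
                      length = integer(), first_base = character(),
                      stringsAsFactors = FALSE))
  }
  len <- GenomicAlignments::cigarWidthAlongQuerySpace(
    alignments$cigar, after.soft.clipping = TRUE
  )
  plus <- alignments$strand == "+"
  pos5 <- ifelse(plus, alignments$start, alignments$end)
  # SAM SEQ is reference-forward; the 5'-most read base of a minus-strand
  # read is the complement of the last SEQ character
  first_fwd <- substr(alignments$seq, 1L, 1L)
  last_fwd <- substr(alignments$seq, nchar(alignments$seq),
                     nchar(alignments$seq))
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  first_base <- ifelse(plus, first_fwd, comp[last_fwd])
  first_base <- ifelse(first_base == "T", "U", first_base)
  out <- data.frame(pos5 = as.integer(pos5), strand = alignments$strand,
                    length = len, first_base = unname(first_base),
                    stringsAsFactors = FALSE)
  out <- out[out$length >= 18L & out$length <= 35L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter small-RNA reads by class
#'
#' piRNAs are 23-29 nt, siRNAs 20-22 nt (centred on the 21 nt Dicer
#' product). Order is preserved.
#'
#' @param reads Data.frame from [smallrna_reads()].
#' @param klass `"piRNA"` or `"siRNA"`.
#' @return Filtered data.frame.
#' @export
filter_by_class <- function(reads, klass = c("piRNA", "siRNA")) {
  klass <- match.arg(klass)
  range <- switch(klass, piRNA = c(23L, 29L), siRNA = c(20L, 22L))
  out <- reads[reads$length >= range[1L] & reads$length <= range[2L], ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read-length histogram
#'
#' @param reads Data.frame from [smallrna_reads()].
#' @return Named integer vector (length -> count).
#' @export
length_histogram <- function(reads) {
  tab <- table(factor(reads$length, levels = 18:35))
  setNames(as.integer(tab), names(tab))
}

#' Fraction of reads with a 5' uridine
#'
#' The 1U bias characteristic of primary piRNAs.
#'
#' @param reads Data.frame from [smallrna_reads()].
#' @return Fraction in [0, 1].
#' @export
first_base_bias <- function(reads) {
  if (nrow(reads) == 0L) {
    stop("no reads; 1U bias undefined", call. = FALSE)
  }
  mean(reads$first_base == "U")
}

#' Per-position sense/antisense 5'-end counts
#'
#' @param reads Data.frame from [smallrna_reads()].
#' @param length Consensus length in bp.
#' @return Data.frame `pos`, `sense`, `antisense`.
#' @export
position_distribution <- function(reads, length) {
  sense <- tabulate(reads$pos5[reads$strand == "+"], nbins = length)
  anti <- tabulate(reads$pos5[reads$strand == "-"], nbins = length)
  data.frame(pos = seq_len(length), sense = sense, antisense = anti)
}

#' Ping-pong signature
#'
#' For sense/antisense piRNA pairs, the number of bases by which the two 5'
#' ends overlap: a sense read with its 5' end at p and an antisense read
#' with its 5' end at p + 9 overlap by d = 10, the hallmark of the
#' Aub/AGO3 amplification loop. Pairs are counted at the level of unique
#' 5'-position pairs weighted by read multiplicity. The z-score of d = 10
#' against all other distances quantifies the signature's strength.
#'
#' @param reads piRNA-class reads (see [filter_by_class()]).
#' @param max_d Largest overlap distance tabulated (default 25).
#' @return List of class `pingpong_signature`: `distance_frequency` (named,
#'   d = 1..max_d, sums to 1 when pairs exist), `pair_count`, `z10`.
#' @export
ping_pong_signature <- function(reads, max_d = 25L) {
  d_levels <- seq_len(max_d)
  empty <- structure(
    list(distance_frequency = setNames(numeric(max_d), d_levels),
         pair_count = 0L, z10 = NA_real_),
    class = "pingpong_signature"
  )
  plus <- reads[reads$strand == "+", , drop = FALSE]
  minus <- reads[reads$strand == "-", , drop = FALSE]
  if (nrow(plus) == 0L || nrow(minus) == 0L) {
    return(empty)
  }
  np <- table(plus$pos5)
  nm <- table(minus$pos5)
  pp <- as.integer(names(np))
  counts <- numeric(max_d)
  for (d in d_levels) {
    # sense 5' at p pairs with antisense 5' at p + d - 1
    q <- as.character(pp + d - 1L)
    hit <- q %in% names(nm)
    counts[d] <- sum(as.numeric(np[hit]) * as.numeric(nm[q[hit]]))
  }
  total <- sum(counts)
  if (total == 0) {
    return(empty)
  }
  others <- counts[-10L]
  z10 <- if (sd(others) > 0) (counts[10L] - mean(others)) / sd(others)
         else NA_real_
  structure(
    list(distance_frequency = setNames(counts / total, d_levels),
         pair_count = total, z10 = z10),
    class = "pingpong_signature"
  )
}

#' @export
print.pingpong_signature <- function(x, ...) {
  mode_d <- if (x$pair_count > 0) {
    names(which.max(x$distance_frequency))
  } else {
    NA
  }
  cat("<pingpong_signature>", x$pair_count, "pairs, modal d =", mode_d,
      ", z10 =", round(x$z10, 2), "\n")
  invisible(x)
}

#' Phasing signature
#'
#' Distances between the 3' end of one piRNA and the 5' start of a
#' downstream piRNA on the same strand, in transcript orientation.
#' Zucchini-mediated phasing produces trails of head-to-tail piRNAs,
#' over-representing a distance of 1 nt (immediately adjacent: the next
#' read starts one base after the previous read ends). Pairs are counted
#' at the level of unique 3'/5' position pairs weighted by read
#' multiplicity, for distances 0..`max_d`; upstream (overlapping) pairs
#' are not tabulated. The two strands are computed separately and summed.
#'
#' @param reads piRNA-class reads.
#' @param max_d Largest distance tabulated (default 25).
#' @return List of class `phasing_signature`: `distance_frequency` (named,
#'   d = 0..max_d), `count`.
#' @export
phasing_signature <- function(reads, max_d = 25L) {
  d_levels <- 0:max_d
  counts <- numeric(max_d + 1L)
  for (s in c("+", "-")) {
    sub <- reads[reads$strand == s, , drop = FALSE]
    if (nrow(sub) < 2L) next
    if (s == "+") {
      n3 <- table(sub$pos5 + sub$length - 1L)
      n5 <- table(sub$pos5)
      sign <- 1L
    } else {
      n3 <- table(sub$pos5 - sub$length + 1L)
      n5 <- table(sub$pos5)
      sign <- -1L   # transcript runs towards lower coordinates
    }
    x3 <- as.integer(names(n3))
    for (d in d_levels) {
      q <- as.character(x3 + sign * d)
      hit <- q %in% names(n5)
      counts[d + 1L] <- counts[d + 1L] +
        sum(as.numeric(n3[hit]) * as.numeric(n5[q[hit]]))
    }
  }
  total <- sum(counts)
  freq <- if (total > 0) counts / total else counts
  structure(
    list(distance_frequency = setNames(freq, d_levels), count = total),
    class = "phasing_signature"
  )
}
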
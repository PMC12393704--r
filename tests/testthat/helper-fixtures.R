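# Shared fixtures, built in code at test time.

fx <- synthetic_pelement()
CONS <- fx$consensus
ANN <- fx$annotation
rm(fx)

REF_CDS_LEN <- sum(vapply(0:3, function(k) {
  f <- feature(ANN, paste0("ORF", k))
  f$end - f$start + 1L
}, integer(1L)))

# three synthetic single-copy genes
make_scg <- function(seed = 42L, n = 3L, len = 2000L) {
  set.seed(seed)
  setNames(
    lapply(seq_len(n), function(i)
      paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE),
             collapse = "")),
    c("tj", "RpL32", "rhi")[seq_len(n)]
  )
}

# hand-built alignment table (the coverage/split-read functions consume
# plain data.frames)
aln_df <- function(start, cigar, read_id = NULL, strand = "+",
                   seq = NA_character_, is_supplementary = FALSE,
                   reference_name = "ref") {
  n <- max(length(start), length(cigar))
  start <- rep_len(start, n)
  cigar <- rep_len(cigar, n)
  if (is.null(read_id)) read_id <- sprintf("r%03d", seq_len(n))
  end <- if (n > 0L) {
    start + GenomicAlignments::cigarWidthAlongReferenceSpace(cigar) - 1L
  } else {
    integer()
  }
  data.frame(
    read_id = rep_len(read_id, n),
    reference_name = rep_len(reference_name, n),
    start = start, end = end,
    strand = rep_len(strand, n), cigar = cigar,
    mapq = rep_len(60L, n),
    seq = rep_len(seq, n), is_supplementary = rep_len(is_supplementary, n),
    stringsAsFactors = FALSE
  )
}

# brute-force per-base coverage oracle: parses CIGARs independently and
# walks every read base by base
coverage_oracle <- function(alignments, reference_length) {
  depth <- integer(reference_length)
  for (i in seq_len(nrow(alignments))) {
    ops <- regmatches(alignments$cigar[i],
                      gregexpr("[0-9]+[MIDNSHP=X]", alignments$cigar[i]))[[1L]]
    pos <- alignments$start[i]
    for (op in ops) {
      len <- as.integer(sub("[A-Z=]$", "", op))
      type <- sub("^[0-9]+", "", op)
      if (type %in% c("M", "=", "X")) {
        for (p in pos:(pos + len - 1L)) depth[p] <- depth[p] + 1L
        pos <- pos + len
      } else if (type %in% c("D", "N")) {
        pos <- pos + len
      }
      # I, S, H, P consume no reference
    }
  }
  depth
}

# small-RNA read table built directly (positions are 5' ends)
sr_df <- function(pos5, strand, length, first_base = "U") {
  n <- max(length(pos5), length(strand), length(length))
  data.frame(pos5 = rep_len(pos5, n), strand = rep_len(strand, n),
             length = rep_len(length, n),
             first_base = rep_len(first_base, n),
             stringsAsFactors = FALSE)
}

# uniform-depth coverage profile via the package's own constructor
uniform_profile <- function(depth, length, n_reads = depth,
                            sample_id = NA_character_) {
  coverage_profile(
    aln_df(start = rep(1L, n_reads),
           cigar = rep(paste0(length, "M"), n_reads)),
    length, sample_id = sample_id
  )
}
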
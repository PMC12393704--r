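# Synthetic-data generation with known ground truth: pooled/individual
# DNA-seq, small-RNA pools and RNA-seq, written as SAM against the
# consensus (plus single-copy genes for DNA-seq).

.sam_header <- function(refs) {
  c("@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(refs), as.integer(refs)))
}

# records: data.frame qname, flag, rname, pos, cigar, seq
.write_sam <- function(records, refs, path) {
  lines <- .sam_header(refs)
  if (nrow(records) > 0L) {
    lines <- c(lines, sprintf(
      "%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
      records$qname, records$flag, records$rname, records$pos,
      records$cigar, records$seq
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

# retained consensus segments of a haplotype -> data.frame(start, end,
# hap_start) with hap_start the haplotype coordinate of each segment start
.haplotype_segments <- function(ids, L) {
  keep <- .runs_of(!.interval_mask(ids, L))
  keep$hap_start <- cumsum(c(1L, (keep$end - keep$start + 1L)))[
    seq_len(nrow(keep))]
  keep
}

# one read of length rl starting at haplotype coordinate a -> pos + cigar
# (M/D interleaved) in consensus space
.read_cigar <- function(segments, a, rl) {
  b <- a + rl - 1L
  seg_end_hap <- segments$hap_start + (segments$end - segments$start)
  touch <- which(seg_end_hap >= a & segments$hap_start <= b)
  spans <- lapply(touch, function(i) {
    s_hap <- max(a, segments$hap_start[i])
    e_hap <- min(b, seg_end_hap[i])
    off <- segments$start[i] - segments$hap_start[i]
    c(s_hap + off, e_hap + off)
  })
  pos <- spans[[1L]][1L]
  cig <- character()
  for (i in seq_along(spans)) {
    if (i > 1L) {
      gap <- spans[[i]][1L] - spans[[i - 1L]][2L] - 1L
      cig <- c(cig, paste0(gap, "D"))
    }
    cig <- c(cig, paste0(spans[[i]][2L] - spans[[i]][1L] + 1L, "M"))
  }
  list(pos = pos, cigar = paste0(cig, collapse = ""))
}

#' Construct a haplotype pool
#'
#' Describes the element composition of a (pooled or individual) sample:
#' the deletion variants segregating in it, their population frequencies,
#' the haploid copy number and the number of diploid individuals.
#'
#' @param variants List of [deletion_variant()] objects with frequencies
#'   set; frequencies must sum to 1.
#' @param haploid_copy_number Mean element copies per haploid genome.
#' @param n_individuals Diploid individuals in the pool (60 for the pooled
#'   sequencing design, 1 for individual flies).
#' @return List of class `haplotype_pool`.
#' @export
haplotype_pool <- function(variants, haploid_copy_number,
                           n_individuals = 60L) {
  freqs <- vapply(variants, function(v) v$frequency, numeric(1L))
  if (abs(sum(freqs) - 1) > 1e-9) {
    stop("variant frequencies must sum to 1", call. = FALSE)
  }
  stopifnot(haploid_copy_number >= 0, n_individuals >= 1L)
  structure(
    list(variants = variants, haploid_copy_number = haploid_copy_number,
         n_individuals = as.integer(n_individuals)),
    class = "haplotype_pool"
  )
}

#' Simulate pooled (or individual) DNA-seq reads
#'
#' Draws the pool's element copies per haploid genome (total copies fixed
#' at `round(copy_number x 2 x n_individuals)`, split multinomially across
#' variants by frequency and uniformly across genomes), then samples reads
#' uniformly along each copy at the per-genome sequencing depth
#' `coverage / (2 x n_individuals)`. Each copy is treated as embedded in
#' flanking genomic DNA: reads overhanging the element boundary are
#' clipped to their element-aligned part, so expected depth is uniform
#' from the first to the last consensus position. Reads crossing a
#' deletion junction are emitted as gapped alignments (CIGAR `D` of the
#' deleted length).
#' Single-copy genes are sequenced at `coverage`. Reads are error-free
#' unless `error_rate > 0` (uniform substitutions).
#'
#' @param pool A [haplotype_pool()].
#' @param consensus A [te_consensus()].
#' @param scg_sequences Named character vector of single-copy-gene
#'   sequences.
#' @param coverage Genome-wide sequencing coverage (x).
#' @param read_length Read length in bp (default 125).
#' @param error_rate Per-base substitution rate (default 0).
#' @param per_individual Write one SAM per individual instead of one pooled
#'   SAM.
#' @param sam_path Output SAM path (a `_<i>` suffix is added per
#'   individual when `per_individual`).
#' @param truth_path Output path for the ground-truth TSV.
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `sam` (path, or vector of per-individual paths),
#'   `truth_path` and `truth` (realised copy number and variant
#'   frequencies).
#' @export
simulate_pool_reads <- function(pool, consensus, scg_sequences, coverage,
                                read_length = 125L, error_rate = 0,
                                per_individual = FALSE,
                                sam_path = tempfile(fileext = ".sam"),
                                truth_path = tempfile(fileext = ".tsv"),
                                seed = 1L) {
  stopifnot(coverage > 0)
  L <- consensus$length
  n_genomes <- 2L * pool$n_individuals
  depth_per_genome <- coverage / n_genomes
  freqs <- vapply(pool$variants, function(v) v$frequency, numeric(1L))

  res <- .with_seed(seed, {
    total_copies <- max(1L, round(pool$haploid_copy_number * n_genomes))
    copies <- as.integer(stats::rmultinom(1L, total_copies, freqs))
    copy_variant <- rep(seq_along(pool$variants), copies)
    copy_genome <- sample.int(n_genomes, total_copies, replace = TRUE)

    segs <- lapply(pool$variants, function(v)
      .haplotype_segments(v$ids, L))
    hap_len <- vapply(pool$variants, function(v)
      nchar(v$reconstructed_sequence), integer(1L))

    # Each insertion sits in flanking genomic DNA: read starts are uniform
    # over [1 - (rl-1), Lh] of the haplotype and alignments are clipped to
    # the element, so depth is uniform up to the element boundaries (the
    # flank-derived bases are not reported, as an aligner would soft-clip
    # them away).
    make_te_reads <- function(copy_idx, tag) {
      rl <- read_length
      recs <- list()
      for (ci in copy_idx) {
        v <- copy_variant[ci]
        Lh <- hap_len[v]
        n <- rpois(1L, depth_per_genome * (Lh + rl - 1L) / rl)
        if (n == 0L) next
        starts <- sample.int(Lh + rl - 1L, n, replace = TRUE) - (rl - 1L)
        a <- pmax(starts, 1L)
        b <- pmin(starts + rl - 1L, Lh)
        hseq <- pool$variants[[v]]$reconstructed_sequence
        rcs <- lapply(seq_len(n), function(i)
          .read_cigar(segs[[v]], a[i], b[i] - a[i] + 1L))
        recs[[length(recs) + 1L]] <- data.frame(
          qname = "", flag = 0L, rname = consensus$name,
          pos = vapply(rcs, function(x) x$pos, integer(1L)),
          cigar = vapply(rcs, function(x) x$cigar, character(1L)),
          seq = substring(hseq, a, b),
          stringsAsFactors = FALSE)
      }
      if (length(recs) == 0L) {
        return(data.frame(qname = character(), flag = integer(),
                          rname = character(), pos = integer(),
                          cigar = character(), seq = character(),
                          stringsAsFactors = FALSE))
      }
      out <- do.call(rbind, recs)
      out$qname <- sprintf("%s_te_%06d", tag, seq_len(nrow(out)))
      out$flag <- sample(c(0L, 16L), nrow(out), replace = TRUE)
      out
    }
    make_scg_reads <- function(cov, tag) {
      rl <- read_length
      recs <- list()
      for (g in names(scg_sequences)) {
        gl <- nchar(scg_sequences[[g]])
        n <- rpois(1L, cov * (gl + rl - 1L) / rl)
        if (n == 0L) next
        starts <- sample.int(gl + rl - 1L, n, replace = TRUE) - (rl - 1L)
        a <- pmax(starts, 1L)
        b <- pmin(starts + rl - 1L, gl)
        recs[[g]] <- data.frame(
          qname = sprintf("%s_%s_%06d", tag, g, seq_len(n)),
          flag = sample(c(0L, 16L), n, replace = TRUE),
          rname = g, pos = a, cigar = paste0(b - a + 1L, "M"),
          seq = substring(scg_sequences[[g]], a, b),
          stringsAsFactors = FALSE)
      }
      do.call(rbind, recs)
    }
    add_errors <- function(recs) {
      if (error_rate <= 0 || nrow(recs) == 0L) return(recs)
      recs$seq <- vapply(recs$seq, function(s) {
        ch <- strsplit(s, "")[[1L]]
        hit <- runif(length(ch)) < error_rate
        ch[hit] <- vapply(ch[hit], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1L))
        paste0(ch, collapse = "")
      }, character(1L), USE.NAMES = FALSE)
      recs
    }
    refs <- c(setNames(L, consensus$name),
              vapply(scg_sequences, nchar, integer(1L)))
    if (per_individual) {
      paths <- character(pool$n_individuals)
      for (i in seq_len(pool$n_individuals)) {
        own <- which(ceiling(copy_genome / 2) == i)
        recs <- rbind(make_te_reads(own, sprintf("ind%02d", i)),
                      make_scg_reads(coverage / pool$n_individuals,
                                     sprintf("ind%02d", i)))
        recs <- add_errors(recs)
        p <- sub("\\.sam$", sprintf("_%02d.sam", i), sam_path)
        .write_sam(recs, refs, p)
        paths[i] <- p
      }
      sam <- paths
    } else {
      recs <- rbind(make_te_reads(seq_len(total_copies), "pool"),
                    make_scg_reads(coverage, "pool"))
      recs <- add_errors(recs)
      .write_sam(recs, refs, sam_path)
      sam <- sam_path
    }
    list(sam = sam,
         copies = copies,
         copy_genome = copy_genome,
         copy_variant = copy_variant,
         total_copies = total_copies)
  })

  truth <- data.frame(
    variant_id = vapply(pool$variants, function(v) v$variant_id,
                        character(1L)),
    intervals = vapply(pool$variants, function(v) {
      if (nrow(v$ids) == 0L) "." else
        paste(sprintf("%d-%d", v$ids$start, v$ids$end), collapse = ";")
    }, character(1L)),
    copies = res$copies,
    frequency = res$copies / res$total_copies,
    copy_number = res$total_copies / n_genomes,
    n_individuals = pool$n_individuals,
    stringsAsFactors = FALSE
  )
  write.table(truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(sam = res$sam, truth_path = truth_path, truth = truth,
       copy_genome = res$copy_genome, copy_variant = res$copy_variant)
}

#' Small-RNA simulation settings
#'
#' Defaults encode the canonical biogenesis geometry: initiator/responder
#' pairs with a 10 nt 5' overlap, piRNA lengths 23-29 nt with mode 26,
#' a strong (0.85) 5'-U bias on initiators, phased trails whose head-to-tail
#' gap peaks at 1 nt, and an siRNA mode centred on 21 nt.
#'
#' @param n_pairs Initiator/responder pairs (or trail seeds / siRNA reads).
#' @param pingpong_offset 5' overlap of a pair in nt (default 10).
#' @param pirna_lengths,pirna_length_probs Support and weights of the piRNA
#'   length distribution.
#' @param initiator_1U_prob Probability that an initiator 5' base is U.
#' @param phasing_gaps,phasing_gap_probs Support and weights of the 3'-to-5'
#'   trail gap distribution (peaked at 1 nt).
#' @param trail_reads Number of phased reads following each trail seed.
#' @param sirna_lengths,sirna_length_probs siRNA length distribution
#'   (mode 21 nt).
#' @param sirna_1U_prob 5'-U probability in siRNA mode (weaker than for
#'   piRNAs).
#' @return List of class `smallrna_sim_spec`.
#' @export
smallrna_sim_spec <- function(n_pairs = 10000L,
                              pingpong_offset = 10L,
                              pirna_lengths = 23:29,
                              pirna_length_probs =
                                c(.05, .1, .2, .3, .2, .1, .05),
                              initiator_1U_prob = 0.85,
                              phasing_gaps = 1:10,
                              phasing_gap_probs =
                                c(.5, .15, .1, .07, .05, .04, .03, .03,
                                  .02, .01),
                              trail_reads = 4L,
                              sirna_lengths = 20:22,
                              sirna_length_probs = c(.15, .7, .15),
                              sirna_1U_prob = 0.5) {
  stopifnot(pingpong_offset >= 1L,
            abs(sum(pirna_length_probs) - 1) < 1e-9,
            abs(sum(phasing_gap_probs) - 1) < 1e-9,
            abs(sum(sirna_length_probs) - 1) < 1e-9)
  if (pingpong_offset > min(pirna_lengths)) {
    stop("ping-pong offset exceeds the shortest read length", call. = FALSE)
  }
  structure(
    list(n_pairs = n_pairs, pingpong_offset = pingpong_offset,
         pirna_lengths = pirna_lengths,
         pirna_length_probs = pirna_length_probs,
         initiator_1U_prob = initiator_1U_prob,
         phasing_gaps = phasing_gaps,
         phasing_gap_probs = phasing_gap_probs,
         trail_reads = trail_reads,
         sirna_lengths = sirna_lengths,
         sirna_length_probs = sirna_length_probs,
         sirna_1U_prob = sirna_1U_prob),
    class = "smallrna_sim_spec"
  )
}

# reads: data.frame(pos5, strand, length, force_u) -> SAM records.
# The 5'-most read base is set to U (T) when force_u, otherwise to a
# non-U base; in forward-strand SAM SEQ this is the first character for
# plus reads and the complement of the last character for minus reads.
.smallrna_records <- function(reads, consensus) {
  n <- nrow(reads)
  plus <- reads$strand == "+"
  pos <- ifelse(plus, reads$pos5, reads$pos5 - reads$length + 1L)
  seq <- substring(consensus$sequence, pos, pos + reads$length - 1L)
  non_u <- c("A", "C", "G")
  first <- ifelse(reads$force_u, "T",
                  non_u[sample.int(3L, n, replace = TRUE)])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  seq <- ifelse(plus,
                paste0(first, substring(seq, 2L)),
                paste0(substring(seq, 1L, reads$length - 1L),
                       unname(comp[first])))
  data.frame(qname = sprintf("sr_%06d", seq_len(n)),
             flag = ifelse(plus, 0L, 16L),
             rname = consensus$name, pos = as.integer(pos),
             cigar = paste0(reads$length, "M"),
             seq = seq, stringsAsFactors = FALSE)
}

#' Simulate a small-RNA pool
#'
#' Three modes: `"pingpong"` draws initiator piRNAs at uniform positions
#' and places a responder on the opposite strand with the configured 5'
#' overlap; `"phased"` additionally emits a head-to-tail trail of piRNAs
#' downstream of each responder with the configured gap distribution;
#' `"sirna"` draws unpaired ~21 nt reads on both strands.
#'
#' @param spec A [smallrna_sim_spec()].
#' @param consensus A [te_consensus()].
#' @param mode Simulation mode.
#' @param sam_path Output SAM path.
#' @param seed Integer seed.
#' @return List with `sam` (path) and `truth` (the spec and mode).
#' @export
simulate_small_rnas <- function(spec, consensus,
                                mode = c("pingpong", "phased", "sirna"),
                                sam_path = tempfile(fileext = ".sam"),
                                seed = 1L) {
  mode <- match.arg(mode)
  L <- consensus$length
  margin <- 60L
  reads <- .with_seed(seed, {
    draw_len <- function(n) sample(spec$pirna_lengths, n, replace = TRUE,
                                   prob = spec$pirna_length_probs)
    if (mode == "sirna") {
      n <- spec$n_pairs
      len <- sample(spec$sirna_lengths, n, replace = TRUE,
                    prob = spec$sirna_length_probs)
      strand <- sample(c("+", "-"), n, replace = TRUE)
      pos5 <- sample.int(L - 2L * margin, n, replace = TRUE) + margin
      out <- data.frame(pos5 = pos5, strand = strand, length = len,
                        force_u = runif(n) < spec$sirna_1U_prob)
    } else {
      n <- spec$n_pairs
      off <- spec$pingpong_offset
      init_strand <- sample(c("+", "-"), n, replace = TRUE)
      init_pos <- sample.int(L - 2L * margin, n, replace = TRUE) + margin
      init_len <- draw_len(n)
      resp_len <- draw_len(n)
      resp_strand <- ifelse(init_strand == "+", "-", "+")
      resp_pos <- ifelse(init_strand == "+",
                         init_pos + off - 1L,
                         init_pos - off + 1L)
      out <- rbind(
        data.frame(pos5 = init_pos, strand = init_strand, length = init_len,
                   force_u = runif(n) < spec$initiator_1U_prob),
        data.frame(pos5 = resp_pos, strand = resp_strand, length = resp_len,
                   force_u = runif(n) < 0.25)
      )
      if (mode == "phased") {
        # head-to-tail trails extending 3' of each responder
        K <- spec$trail_reads
        gaps <- matrix(sample(spec$phasing_gaps, n * K, replace = TRUE,
                              prob = spec$phasing_gap_probs), n, K)
        lens <- matrix(draw_len(n * K), n, K)
        dirs <- ifelse(resp_strand == "+", 1L, -1L)
        cur3 <- ifelse(resp_strand == "+",
                       resp_pos + resp_len - 1L,
                       resp_pos - resp_len + 1L)
        trail <- vector("list", K)
        for (k in seq_len(K)) {
          p5 <- cur3 + dirs * gaps[, k]
          cur3 <- p5 + dirs * (lens[, k] - 1L)
          trail[[k]] <- data.frame(
            pos5 = p5, strand = resp_strand, length = lens[, k],
            force_u = runif(n) < spec$initiator_1U_prob)
        }
        tr <- do.call(rbind, trail)
        ok <- tr$pos5 - tr$length + 1L >= 1L &
          tr$pos5 + tr$length - 1L <= L
        out <- rbind(out, tr[ok, , drop = FALSE])
      }
      out
    }
  })
  recs <- .with_seed(seed + 1L, .smallrna_records(reads, consensus))
  .write_sam(recs, setNames(L, consensus$name), sam_path)
  list(sam = sam_path, truth = list(mode = mode, spec = spec,
                                    n_reads = nrow(reads)))
}

#' Simulate RNA-seq reads over the element
#'
#' Emits `junction_reads` reads across each intron's donor site; each is
#' spliced (an `N` gap exactly matching the intron) with the intron's
#' configured rate, and retained (contiguous alignment through the donor)
#' otherwise. Optional uniform background reads support expression
#' estimates; reads are antisense with probability `antisense_fraction`.
#'
#' @param consensus A [te_consensus()].
#' @param annotation Annotation data.frame with IVS1-IVS3.
#' @param splicing_rates Named vector of per-intron splicing probabilities
#'   (names `IVS1`-`IVS3`).
#' @param junction_reads Reads per intron junction.
#' @param n_background Additional uniform reads (default 0).
#' @param antisense_fraction Probability of an antisense read (default 0).
#' @param read_length Read length in bp (default 100).
#' @param library_size Total mapped reads of the library the sample
#'   represents (metadata for srpm; default 1e6).
#' @param sam_path Output SAM path.
#' @param seed Integer seed.
#' @return List with `sam`, `library_size` and `truth` (rates and realised
#'   spliced counts).
#' @export
simulate_rnaseq <- function(consensus, annotation, splicing_rates,
                            junction_reads = 1000L, n_background = 0L,
                            antisense_fraction = 0, read_length = 100L,
                            library_size = 1e6,
                            sam_path = tempfile(fileext = ".sam"),
                            seed = 1L) {
  if (any(splicing_rates < 0 | splicing_rates > 1)) {
    stop("splicing rates must lie in [0, 1]", call. = FALSE)
  }
  L <- consensus$length
  res <- .with_seed(seed, {
    recs <- list()
    spliced_n <- setNames(integer(3L), paste0("IVS", 1:3))
    for (k in 1:3) {
      id <- paste0("IVS", k)
      iv <- feature(annotation, id)
      rate <- if (id %in% names(splicing_rates)) splicing_rates[[id]] else 0
      if (junction_reads == 0L) next
      anchor <- sample(10:(read_length - 10L), junction_reads,
                       replace = TRUE)
      spliced <- runif(junction_reads) < rate
      spliced_n[id] <- sum(spliced)
      pos <- iv$start - anchor
      ivlen <- iv$end - iv$start + 1L
      cigar <- ifelse(spliced,
                      sprintf("%dM%dN%dM", anchor, ivlen,
                              read_length - anchor),
                      paste0(read_length, "M"))
      seq <- ifelse(spliced,
                    paste0(substring(consensus$sequence, pos,
                                     iv$start - 1L),
                           substring(consensus$sequence, iv$end + 1L,
                                     iv$end + read_length - anchor)),
                    substring(consensus$sequence, pos,
                              pos + read_length - 1L))
      recs[[id]] <- data.frame(
        qname = sprintf("rna_%s_%06d", id, seq_len(junction_reads)),
        flag = ifelse(runif(junction_reads) < antisense_fraction, 16L, 0L),
        rname = consensus$name, pos = pos, cigar = cigar, seq = seq,
        stringsAsFactors = FALSE)
    }
    if (n_background > 0L) {
      pos <- sample.int(L - read_length + 1L, n_background, replace = TRUE)
      recs[["bg"]] <- data.frame(
        qname = sprintf("rna_bg_%06d", seq_len(n_background)),
        flag = ifelse(runif(n_background) < antisense_fraction, 16L, 0L),
        rname = consensus$name, pos = pos,
        cigar = paste0(read_length, "M"),
        seq = substring(consensus$sequence, pos, pos + read_length - 1L),
        stringsAsFactors = FALSE)
    }
    list(recs = do.call(rbind, recs), spliced_n = spliced_n)
  })
  .write_sam(res$recs, setNames(L, consensus$name), sam_path)
  list(sam = sam_path, library_size = library_size,
       truth = list(splicing_rates = splicing_rates,
                    spliced_counts = res$spliced_n,
                    junction_reads = junction_reads))
}
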
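# Consensus sequence and feature anatomy of the transposable element.

FEATURE_LABELS <- c(
  "ORF0", "ORF1", "ORF2", "ORF3",
  "IVS1", "IVS2", "IVS3",
  "TIR_left", "TIR_right",
  "transposase_binding_site", "DNA_binding_domain"
)

#' Construct a TE consensus object
#'
#' A consensus is the canonical sequence of a transposable-element family,
#' against which all reads, deletions and features are expressed. Coordinates
#' throughout the package are 1-based closed intervals on the consensus
#' forward strand.
#'
#' @param name Identifier of the element (e.g. `"PPI251"`).
#' @param sequence DNA string over `A`, `C`, `G`, `T`, `N`.
#' @return An object of class `te_consensus` with fields `name`, `sequence`
#'   and `length`.
#' @export
te_consensus <- function(name, sequence) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) < 1L) {
    stop("consensus sequence must be non-empty", call. = FALSE)
  }
  if (grepl("[^ACGTN]", sequence)) {
    stop("consensus contains non-nucleotide characters", call. = FALSE)
  }
  structure(
    list(name = name, sequence = sequence, length = nchar(sequence)),
    class = "te_consensus"
  )
}

#' @export
print.te_consensus <- function(x, ...) {
  cat("<te_consensus>", x$name, "-", x$length, "bp\n")
  invisible(x)
}

#' Load a TE consensus from a FASTA file
#'
#' Reads the first record of a FASTA file, uppercases it and validates the
#' nucleotide alphabet.
#'
#' @param fasta_path Path to a FASTA file with at least one record.
#' @return A [te_consensus()] object.
#' @export
load_consensus <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path, call. = FALSE)
  }
  set <- tryCatch(
    suppressWarnings(Biostrings::readDNAStringSet(fasta_path)),
    error = function(e) stop("not a valid nucleotide FASTA: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) {
    stop("FASTA file contains no records", call. = FALSE)
  }
  name <- sub("\\s.*$", "", names(set)[1L])
  te_consensus(name, as.character(set[[1L]]))
}

#' Load the feature annotation of a consensus
#'
#' Reads a GFF3 file describing the anatomy of the element: the four open
#' reading frames (`ORF0`-`ORF3`), the three introns (`IVS1`-`IVS3`), the
#' terminal inverted repeats, transposase-binding sites and the DNA-binding
#' domain (inside ORF0). Intervals are validated against the consensus and
#' the expected topology (ORFs ascending and non-overlapping, each IVS
#' between its flanking ORFs, DNA-binding domain inside ORF0).
#'
#' @param gff_path Path to a GFF3 file whose seqid matches the consensus name.
#' @param consensus A [te_consensus()] object.
#' @return A data.frame with columns `feature_label`, `start`, `end`,
#'   `frame_offset` (NA for non-coding features).
#' @export
load_annotation <- function(gff_path, consensus) {
  if (!file.exists(gff_path)) {
    stop("annotation file not found: ", gff_path, call. = FALSE)
  }
  gr <- tryCatch(
    rtracklayer::import(gff_path, format = "gff3"),
    error = function(e) stop("cannot parse GFF3: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (length(gr) == 0L) {
    warning("annotation file contains no features")
    return(data.frame(feature_label = character(), start = integer(),
                      end = integer(), frame_offset = integer()))
  }
  seqids <- as.character(GenomicRanges::seqnames(gr))
  if (!all(seqids == consensus$name)) {
    stop("annotation seqid does not match consensus name '", consensus$name,
         "'", call. = FALSE)
  }
  phase <- if ("phase" %in% names(S4Vectors::mcols(gr))) {
    as.integer(as.character(S4Vectors::mcols(gr)$phase))
  } else {
    rep(NA_integer_, length(gr))
  }
  ann <- data.frame(
    feature_label = as.character(S4Vectors::mcols(gr)$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    frame_offset = phase,
    stringsAsFactors = FALSE
  )
  validate_annotation(ann, consensus)
  ann[order(ann$start), , drop = FALSE]
}

#' Validate a feature annotation against a consensus
#'
#' @param ann Annotation data.frame as from [load_annotation()].
#' @param consensus A [te_consensus()] object.
#' @return Invisibly `TRUE`; stops with an informative error on violation.
#' @export
validate_annotation <- function(ann, consensus) {
  bad <- setdiff(unique(ann$feature_label), FEATURE_LABELS)
  if (length(bad) > 0L) {
    stop("unknown feature label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  .check_intervals(ann, consensus$length)
  orfs <- ann[grepl("^ORF", ann$feature_label), , drop = FALSE]
  orfs <- orfs[order(orfs$feature_label), , drop = FALSE]
  if (nrow(orfs) > 1L) {
    if (is.unsorted(orfs$start) ||
        any(orfs$start[-1L] <= orfs$end[-nrow(orfs)])) {
      stop("ORFs must be non-overlapping and in ascending order",
           call. = FALSE)
    }
  }
  for (k in 1:3) {
    ivs <- ann[ann$feature_label == paste0("IVS", k), , drop = FALSE]
    up <- orfs[orfs$feature_label == paste0("ORF", k - 1L), , drop = FALSE]
    dn <- orfs[orfs$feature_label == paste0("ORF", k), , drop = FALSE]
    if (nrow(ivs) == 1L && nrow(up) == 1L && nrow(dn) == 1L) {
      if (!(ivs$start > up$end && ivs$end < dn$start)) {
        stop("IVS", k, " must lie between ORF", k - 1L, " and ORF", k,
             call. = FALSE)
      }
    }
  }
  dbd <- ann[ann$feature_label == "DNA_binding_domain", , drop = FALSE]
  orf0 <- ann[ann$feature_label == "ORF0", , drop = FALSE]
  if (nrow(dbd) == 1L && nrow(orf0) == 1L) {
    if (!(dbd$start >= orf0$start && dbd$end <= orf0$end)) {
      stop("DNA_binding_domain must lie inside ORF0", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write a feature annotation to GFF3
#'
#' Inverse of [load_annotation()]: intervals round-trip exactly.
#'
#' @param ann Annotation data.frame.
#' @param path Output file path.
#' @param seqid Consensus name used as the GFF3 seqid.
#' @return The path, invisibly.
#' @export
write_annotation <- function(ann, path, seqid) {
  lines <- c("##gff-version 3")
  if (nrow(ann) > 0L) {
    phase <- ifelse(is.na(ann$frame_offset), ".",
                    as.character(ann$frame_offset))
    lines <- c(lines, sprintf(
      "%s\tpinvade\t%s\t%d\t%d\t.\t+\t%s\tID=%s_%d",
      seqid, ann$feature_label, ann$start, ann$end, phase,
      ann$feature_label, seq_len(nrow(ann))
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Feature intervals by label
#'
#' @param ann Annotation data.frame.
#' @param label Feature label to extract.
#' @return Data.frame subset, ordered by start.
#' @export
feature <- function(ann, label) {
  out <- ann[ann$feature_label == label, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Synthetic P-element consensus and annotation
#'
#' Builds a deterministic 2907 bp stand-in for the P-element consensus
#' together with a plausible feature anatomy: four ORFs separated by three
#' introns with canonical GT..AG boundaries, 31 bp terminal inverted repeats,
#' transposase-binding sites near both ends, and a DNA-binding domain inside
#' ORF0. The germline coding sequence (ORF0-ORF3 concatenated) starts with
#' ATG, is free of internal stop codons and ends with TAA. The sequence is
#' synthetic: the element's true sequence is not bundled, and the exact
#' feature coordinates are placeholders with the correct topology, not
#' published values.
#'
#' @param seed Integer seed controlling the synthetic sequence (the bundled
#'   fixture uses the default).
#' @return A list with elements `consensus` ([te_consensus()]) and
#'   `annotation` (data.frame).
#' @export
synthetic_pelement <- function(seed = 2907L) {
  L <- 2907L
  ann <- data.frame(
    feature_label = c("TIR_left", "transposase_binding_site", "ORF0",
                      "DNA_binding_domain", "IVS1", "ORF1", "IVS2", "ORF2",
                      "IVS3", "ORF3", "transposase_binding_site", "TIR_right"),
    start = c(1L, 48L, 153L, 178L, 443L, 502L, 1168L, 1222L,
              1947L, 2138L, 2855L, 2877L),
    end = c(31L, 68L, 442L, 360L, 501L, 1167L, 1221L, 1946L,
            2137L, 2706L, 2871L, 2907L),
    stringsAsFactors = FALSE
  )
  orfs <- feature(ann, "ORF0")
  for (k in 1:3) orfs <- rbind(orfs, feature(ann, paste0("ORF", k)))
  cum <- cumsum(c(0L, orfs$end - orfs$start + 1L))
  frame_offset <- rep(NA_integer_, nrow(ann))
  for (k in 0:3) {
    frame_offset[ann$feature_label == paste0("ORF", k)] <- cum[k + 1L] %% 3L
  }
  ann$frame_offset <- frame_offset
  cds_len <- cum[5L]
  stopifnot(cds_len %% 3L == 0L)

  seq <- .with_seed(seed, {
    base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                c("A", "C", "G", "T")), 1L, paste0,
                    collapse = "")
    sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
    n_mid <- cds_len %/% 3L - 2L
    cds <- paste0("ATG", paste0(sample(sense, n_mid, replace = TRUE),
                                collapse = ""), "TAA")
    cds_chars <- strsplit(cds, "")[[1L]]
    pos <- unlist(mapply(seq, orfs$start, orfs$end, SIMPLIFY = FALSE))
    base[pos] <- cds_chars
    for (k in 1:3) {
      iv <- feature(ann, paste0("IVS", k))
      base[iv$start:(iv$start + 1L)] <- c("G", "T")
      base[(iv$end - 1L):iv$end] <- c("A", "G")
    }
    tir <- paste0(base[1:31], collapse = "")
    base[2877:2907] <- strsplit(.revcomp(tir), "")[[1L]]
    paste0(base, collapse = "")
  })
  cons <- te_consensus("PPI251", seq)
  validate_annotation(ann, cons)
  list(consensus = cons, annotation = ann)
}
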
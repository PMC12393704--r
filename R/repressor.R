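# Repressor classification of internally deleted variants: sequence
# reconstruction, germline CDS assembly, ORF-defect scanning and the
# repressor criteria (transposase interrupted + DNA-binding domain intact).

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reconstruct the sequence of a deletion variant
#'
#' Concatenates the retained consensus segments, in order, after removing
#' the deleted intervals.
#'
#' @param consensus A [te_consensus()] object.
#' @param ids Data.frame of non-overlapping deleted intervals (`start`,
#'   `end`); may be empty.
#' @return DNA string of the reconstructed variant.
#' @export
reconstruct_variant_sequence <- function(consensus, ids) {
  .check_intervals(ids, consensus$length)
  if (is.null(ids) || nrow(ids) == 0L) {
    return(consensus$sequence)
  }
  if (.intervals_overlap(ids)) {
    stop("deleted intervals overlap", call. = FALSE)
  }
  keep <- !.interval_mask(ids, consensus$length)
  paste0(strsplit(consensus$sequence, "")[[1L]][keep], collapse = "")
}

#' Construct a deletion variant
#'
#' @param variant_id Identifier.
#' @param ids Data.frame of non-overlapping deleted intervals; may be empty
#'   (a full-length variant).
#' @param consensus A [te_consensus()] object.
#' @param frequency Population frequency in [0, 1].
#' @return Object of class `deletion_variant`.
#' @export
deletion_variant <- function(variant_id, ids, consensus, frequency = NA_real_) {
  seq <- reconstruct_variant_sequence(consensus, ids)
  if (is.null(ids)) {
    ids <- data.frame(start = integer(), end = integer())
  }
  structure(
    list(variant_id = variant_id, ids = ids,
         reconstructed_sequence = seq, frequency = frequency),
    class = "deletion_variant"
  )
}

# ordered consensus positions of the reference germline transcript
# (ORF0..ORF3, introns spliced)
.germline_positions <- function(annotation) {
  pos <- integer()
  for (k in 0:3) {
    orf <- feature(annotation, paste0("ORF", k))
    if (nrow(orf) != 1L) {
      stop("annotation must define ORF", k, call. = FALSE)
    }
    pos <- c(pos, orf$start:orf$end)
  }
  pos
}

#' Assemble the germline coding sequence of a variant
#'
#' The germline mRNA has all three introns (IVS1-IVS3) spliced out; the
#' coding sequence is the concatenation of the four ORFs, mapped through the
#' variant's deletions. An intron whose donor or acceptor (its first or last
#' two bases) is destroyed by a deletion can no longer be spliced and its
#' remaining sequence is retained in the message; an intron deleted entirely
#' contributes nothing.
#'
#' The result carries attributes used by [scan_orf_defects()]:
#' `junctions` (1-based CDS positions of the first base after each
#' deletion/retention junction), `shifted` (whether the reading frame
#' downstream of each junction is offset relative to the reference frame)
#' and `coding_deleted` (whether any reference coding base is missing).
#'
#' @param variant A [deletion_variant()].
#' @param annotation Annotation data.frame defining ORF0-3 and IVS1-3.
#' @param consensus The [te_consensus()] the variant was reconstructed from.
#' @return DNA string (possibly empty) with junction attributes.
#' @export
germline_cds <- function(variant, annotation, consensus) {
  for (k in 1:3) {
    if (nrow(feature(annotation, paste0("IVS", k))) != 1L) {
      stop("annotation must define IVS", k, call. = FALSE)
    }
  }
  L <- consensus$length
  deleted <- .interval_mask(variant$ids, L)
  ref_pos <- .germline_positions(annotation)

  # introns whose splice sites are destroyed are retained
  transcript_pos <- ref_pos
  for (k in 1:3) {
    iv <- feature(annotation, paste0("IVS", k))
    donor <- iv$start:(iv$start + 1L)
    acceptor <- (iv$end - 1L):iv$end
    if (any(deleted[donor]) || any(deleted[acceptor])) {
      transcript_pos <- sort(unique(c(transcript_pos, iv$start:iv$end)))
    }
  }
  transcript_pos <- sort(transcript_pos)
  var_pos <- transcript_pos[!deleted[transcript_pos]]

  chars <- strsplit(consensus$sequence, "")[[1L]]
  cds <- paste0(chars[var_pos], collapse = "")

  # reference CDS index of each consensus position (NA for intronic bases)
  ref_index <- rep(NA_integer_, L)
  ref_index[ref_pos] <- seq_along(ref_pos)

  # Junctions: variant CDS positions (index of first base after the event)
  # where the reference transcript is disrupted, i.e. coding bases were
  # skipped or intronic bases inserted. Contiguity in the reference
  # transcript (including a normal splice) and plain genomic continuation
  # within a retained intron are not junctions; a retained intron's first
  # base is (the retention inserts non-reference sequence into the frame).
  junctions <- integer()
  shifted <- logical()
  if (length(var_pos) > 1L) {
    is_ref <- !is.na(ref_index[var_pos])
    ref_idx <- ref_index[var_pos]
    # frame agreement of each reference-derived base with the intact frame
    frame_ok <- ((seq_along(var_pos) - 1L) %% 3L) == ((ref_idx - 1L) %% 3L)
    for (j in 2:length(var_pos)) {
      is_junction <-
        if (is_ref[j] && is_ref[j - 1L]) {
          ref_idx[j] != ref_idx[j - 1L] + 1L       # coding deletion
        } else if (!is_ref[j] && !is_ref[j - 1L]) {
          var_pos[j] != var_pos[j - 1L] + 1L       # deletion inside intron
        } else if (!is_ref[j]) {
          TRUE                                     # retained intron begins
        } else {
          var_pos[j] != var_pos[j - 1L] + 1L       # intron->exon with a gap
        }
      if (is_junction) {
        after <- which(is_ref & seq_along(var_pos) >= j)
        junctions <- c(junctions, j)
        shifted <- c(shifted,
                     if (length(after) == 0L) FALSE
                     else !frame_ok[after[1L]])
      }
    }
  }

  attr(cds, "junctions") <- junctions
  attr(cds, "junction_consensus") <- var_pos[junctions]
  attr(cds, "shifted") <- shifted
  attr(cds, "coding_deleted") <- any(deleted[ref_pos])
  cds
}

#' Scan a coding sequence for translation defects
#'
#' Translates the CDS from frame 0 and reports the transposase status:
#' `intact` when the reading frame matches the reference with no internal
#' stop codon; `premature_stop` when a stop codon occurs before the final
#' codon; `frameshift` when a junction offsets the downstream frame by a
#' non-multiple of 3; `deleted` when coding sequence is missing without
#' creating either defect (translation still interrupted), or when the CDS
#' is empty. When several defects occur, the first one 5'-to-3' is reported.
#'
#' @param cds DNA string, typically from [germline_cds()] (its junction
#'   attributes are used when present).
#' @param reference_cds_length Length of the intact reference CDS in bp.
#' @param junctions,shifted Optional junction positions and frame-offset
#'   flags overriding the attributes of `cds`.
#' @return List with `transposase_status` and `defect_positions` (1-based
#'   CDS coordinates of the reported defects).
#' @export
scan_orf_defects <- function(cds, reference_cds_length,
                             junctions = attr(cds, "junctions"),
                             shifted = attr(cds, "shifted")) {
  n <- nchar(cds)
  if (n == 0L) {
    return(list(transposase_status = "deleted", defect_positions = integer()))
  }
  if (is.null(junctions)) junctions <- integer()
  if (is.null(shifted)) shifted <- logical(length(junctions))
  coding_deleted <- isTRUE(attr(cds, "coding_deleted")) ||
    (length(junctions) > 0L)

  first_shift <- if (any(shifted)) min(junctions[shifted]) else NA_integer_

  # first internal stop codon (a stop occupying the final 3 bases of an
  # in-frame CDS is the reference terminator, not a defect)
  codon_starts <- seq.int(1L, n - 2L, by = 3L)
  codons <- substring(cds, codon_starts, codon_starts + 2L)
  stops <- codon_starts[codons %in% STOP_CODONS]
  internal <- stops[stops + 2L < n]
  first_stop <- if (length(internal) > 0L) internal[1L] else NA_integer_

  if (!is.na(first_shift) &&
      (is.na(first_stop) || first_shift <= first_stop)) {
    return(list(transposase_status = "frameshift",
                defect_positions = first_shift))
  }
  if (!is.na(first_stop)) {
    return(list(transposase_status = "premature_stop",
                defect_positions = first_stop))
  }
  if (coding_deleted || n < reference_cds_length) {
    return(list(transposase_status = "deleted",
                defect_positions = junctions))
  }
  list(transposase_status = "intact", defect_positions = integer())
}

# status of the DNA-binding domain given the variant's deletions and the
# frame state upstream of the domain's end
.dbd_status <- function(variant, annotation, consensus) {
  dbd <- feature(annotation, "DNA_binding_domain")
  if (nrow(dbd) != 1L) {
    stop("annotation must define DNA_binding_domain", call. = FALSE)
  }
  deleted <- .interval_mask(variant$ids, consensus$length)
  span <- dbd$start:dbd$end
  if (all(deleted[span])) {
    return("absent")
  }
  if (any(deleted[span])) {
    return("truncated")
  }
  # frame up to the domain's end must be unshifted
  cds <- germline_cds(variant, annotation, consensus)
  jc <- attr(cds, "junction_consensus")
  shifted <- attr(cds, "shifted")
  if (length(shifted) > 0L && any(shifted & jc <= dbd$end)) {
    return("truncated")
  }
  "intact"
}

#' Classify a deletion variant by the repressor criteria
#'
#' A putative repressor of transposition must (i) have interrupted
#' transposase translation (by deletion, frameshift or premature stop) and
#' (ii) retain an intact DNA-binding domain in ORF0, so that the defective
#' protein can still occupy transposase-binding sites. Variants with an
#' intact transposase are autonomous; variants with a truncated domain are
#' ambiguous non-autonomous; all remaining non-autonomous variants lack the
#' domain.
#'
#' @param variant A [deletion_variant()].
#' @param annotation Annotation data.frame.
#' @param consensus The [te_consensus()].
#' @return List of class `repressor_call`: `variant_id`,
#'   `transposase_status`, `dbd_status`, `klass`, `frequency`.
#' @export
classify_variant <- function(variant, annotation, consensus) {
  ref_cds_len <- length(.germline_positions(annotation))
  cds <- germline_cds(variant, annotation, consensus)
  scan <- scan_orf_defects(cds, ref_cds_len)
  dbd <- .dbd_status(variant, annotation, consensus)
  klass <- if (scan$transposase_status == "intact") {
    "autonomous_full_length"
  } else if (dbd == "intact") {
    "putative_repressor"
  } else if (dbd == "truncated") {
    "ambiguous_nonautonomous"
  } else {
    "other_nonautonomous"
  }
  structure(
    list(variant_id = variant$variant_id,
         transposase_status = scan$transposase_status,
         dbd_status = dbd, klass = klass,
         frequency = variant$frequency),
    class = "repressor_call"
  )
}

#' Summarise variant classes of a replicate
#'
#' Sums variant frequencies per class (as percentages) and reports the
#' putative-repressor percentage as a range: the lower bound counts definite
#' putative repressors only, the upper bound additionally includes
#' ambiguous non-autonomous variants (DNA-binding domain truncated, repressor
#' function uncertain).
#'
#' @param calls List of [classify_variant()] results.
#' @param full_length Optional [full_length_frequency()] estimate; reported
#'   as `full_length_percent`.
#' @return List of class `class_summary`: `class_percent` (named numeric),
#'   `repressor_range` (c(lower, upper), %), `full_length_percent`.
#' @export
summarize_classes <- function(calls, full_length = NULL) {
  klasses <- c("autonomous_full_length", "putative_repressor",
               "ambiguous_nonautonomous", "other_nonautonomous")
  pct <- setNames(numeric(length(klasses)), klasses)
  for (call in calls) {
    f <- call$frequency
    if (is.na(f)) {
      stop("variant '", call$variant_id, "' has no frequency", call. = FALSE)
    }
    pct[call$klass] <- pct[call$klass] + 100 * f
  }
  structure(
    list(class_percent = pct,
         repressor_range = c(
           lower = unname(pct["putative_repressor"]),
           upper = unname(pct["putative_repressor"] +
                            pct["ambiguous_nonautonomous"])
         ),
         full_length_percent = if (is.null(full_length)) NA_real_ else
           100 * full_length$frequency),
    class = "class_summary"
  )
}

#' @export
print.class_summary <- function(x, ...) {
  cat("<class_summary>\n")
  for (k in names(x$class_percent)) {
    cat(sprintf("  %-24s %5.1f%%\n", k, x$class_percent[k]))
  }
  cat(sprintf("  repressor range          %.0f-%.0f%%\n",
              x$repressor_range["lower"], x$repressor_range["upper"]))
  if (!is.na(x$full_length_percent)) {
    cat(sprintf("  full-length              %5.1f%%\n",
                x$full_length_percent))
  }
  invisible(x)
}
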
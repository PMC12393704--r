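# Internal helpers shared across modules.

#' @importFrom stats rpois runif setNames sd
#' @importFrom utils read.table write.table
NULL

# 1-based closed intervals as a two-column data.frame (start, end).
.check_intervals <- function(ids, length = NULL) {
  if (is.null(ids) || nrow(ids) == 0L) {
    return(invisible(TRUE))
  }
  stopifnot(all(c("start", "end") %in% names(ids)))
  if (any(ids$start > ids$end)) {
    stop("interval with start > end", call. = FALSE)
  }
  if (!is.null(length) && (any(ids$start < 1L) || any(ids$end > length))) {
    stop("interval out of bounds [1, ", length, "]", call. = FALSE)
  }
  invisible(TRUE)
}

.intervals_overlap <- function(ids) {
  if (nrow(ids) < 2L) {
    return(FALSE)
  }
  o <- order(ids$start)
  any(ids$start[o][-1L] <= ids$end[o][-nrow(ids)])
}

# positions covered by any interval, as a logical mask of length L
.interval_mask <- function(ids, L) {
  mask <- logical(L)
  if (!is.null(ids) && nrow(ids) > 0L) {
    for (i in seq_len(nrow(ids))) {
      mask[ids$start[i]:ids$end[i]] <- TRUE
    }
  }
  mask
}

# maximal runs of TRUE in a logical vector -> data.frame(start, end)
.runs_of <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Evaluate expr with a private RNG stream derived from `seed`, restoring the
# caller's .Random.seed afterwards.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
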
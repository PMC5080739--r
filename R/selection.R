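# Greedy reduction of a read's initial alignments to an "optimal set".
#
# Iteratively: move the best-scoring alignment (together with any co-optimal
# alignments of equal score and identical read interval -- multi-hit
# ambiguity) into the set, discard every remaining alignment that overlaps a
# member by more than the threshold fraction, and repeat until no alignment
# remains. Overlap is measured on read coordinates only: reference overlap is
# legitimate for duplicated segments, read overlap signals mutually exclusive
# explanations of the same bases.

#' Overlap fraction of two alignments of the same read
#'
#' The shared read-interval length divided by the length of the shorter
#' alignment, so a nested alignment scores 1.
#'
#' @param a,b Single alignment rows (one-row data frames) with the same
#'   `read_id`.
#' @return A fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(a, b) {
  if (a$read_id != b$read_id) {
    stop("overlap_fraction: alignments belong to different reads (",
         a$read_id, ", ", b$read_id, ")")
  }
  inter <- min(a$read_end, b$read_end) - max(a$read_start, b$read_start)
  if (inter <= 0) return(0)
  inter / min(a$read_end - a$read_start, b$read_end - b$read_start)
}

#' Does a candidate alignment conflict with a selected one?
#'
#' TRUE when the overlap fraction strictly exceeds the threshold, unless the
#' two are co-optimal multi-hits (equal score and identical read interval),
#' which are exempt from mutual filtering.
#'
#' @param candidate,selected Single alignment rows.
#' @param threshold Overlap fraction above which alignments conflict
#'   (default 0.5, i.e. "more than half").
#' @return Logical scalar.
#' @export
conflicts <- function(candidate, selected, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  if (candidate$score == selected$score &&
      candidate$read_start == selected$read_start &&
      candidate$read_end == selected$read_end) {
    return(FALSE)
  }
  overlap_fraction(candidate, selected) > threshold
}

# canonical total order making the greedy loop order-independent
canonical_order <- function(aln) {
  aln[order(-aln$score, aln$read_start, aln$ref_start, aln$strand), ]
}

#' Greedy optimal set of alignments for one read
#'
#' @param alignments Alignment tibble for a single read (any order).
#' @param threshold Conflict threshold, see [conflicts()].
#' @return The surviving alignments, ordered by `read_start`, with
#'   `provenance = "selection"`. Empty input yields an empty set.
#' @export
optimal_alignment_set <- function(alignments, threshold = 0.5) {
  if (nrow(alignments) == 0) return(empty_alignments())
  stopifnot(length(unique(alignments$read_id)) == 1)
  rem <- canonical_order(alignments)
  rs <- rem$read_start
  re <- rem$read_end
  sc <- rem$score
  len <- re - rs
  active <- rep(TRUE, nrow(rem))
  selected <- rep(FALSE, nrow(rem))
  while (any(active)) {
    top <- which(active)[1]
    # co-optimal group: equal score and identical read interval enter together
    grp <- active & sc == sc[top] & rs == rs[top] & re == re[top]
    selected[grp] <- TRUE
    active[grp] <- FALSE
    cand <- which(active)
    if (length(cand) > 0) {
      # all group members share one read interval, so one conflict test
      # covers the group; equal-score identical-interval candidates were
      # already absorbed into the group above
      inter <- pmin(re[cand], re[top]) - pmax(rs[cand], rs[top])
      frac <- ifelse(inter <= 0, 0, inter / pmin(len[cand], len[top]))
      active[cand[frac > threshold]] <- FALSE
    }
  }
  out <- rem[selected, ]
  out$provenance <- "selection"
  out[order(out$read_start, out$ref_start), ]
}
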
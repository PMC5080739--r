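# Elimination of residual few-base overlaps between surviving alignments.
# For each overlapping pair, every cut point in the overlap is evaluated; the
# pair is trimmed at the cut maximizing the total bonus score, where each
# aligned base whose reference position lies in a V, D or J region earns one
# extra point (C-region bases earn none). This pulls cut points onto exon
# boundaries.

#' Bonus score of an alignment
#'
#' The alignment score plus one point per aligned read base (match or
#' mismatch column) whose reference position lies inside any V, D or J
#' region.
#'
#' @param a A single alignment row with a valid CIGAR.
#' @param ref A [gene_reference()].
#' @param params An [align_params()] list (scoring scheme).
#' @return Integer bonus score.
#' @export
bonus_score <- function(a, ref, params = align_params()) {
  tab <- cigar_table(a$cigar)
  aligned <- tab$op %in% c("=", "X")
  bonus <- sum(ref$vdj_mask[a$ref_start + tab$ref_off[aligned] + 1L])
  as.integer(a$score + bonus)
}

#' Trim an alignment to a window of forward read positions
#'
#' Keeps only trace columns whose read position lies in `[keep_lo, keep_hi)`,
#' strips boundary gap columns, and re-derives coordinates, score and
#' identity. A cut inside a reference-gap run resolves to the nearest read
#' position on its left.
#'
#' @param a A single alignment row.
#' @param keep_lo,keep_hi Forward read coordinates (0-based half-open).
#' @param read_len Length of the read (needed for minus-strand rows).
#' @param params An [align_params()] list.
#' @return The trimmed row, or `NULL` if fewer than one aligned base remains.
#' @export
trim_alignment <- function(a, keep_lo, keep_hi, read_len,
                           params = align_params()) {
  ivl <- adjusted_read_interval(a, read_len)
  if (a$strand == "+") {
    alo <- max(keep_lo, ivl[1]); ahi <- min(keep_hi, ivl[2])
  } else {
    alo <- max(read_len - keep_hi, ivl[1])
    ahi <- min(read_len - keep_lo, ivl[2])
  }
  if (ahi <= alo) return(NULL)
  tab <- cigar_table(a$cigar)
  pos <- ivl[1] + tab$read_off
  keep <- pos >= alo & pos < ahi
  if (!any(keep)) return(NULL)
  idx <- which(keep)
  ops <- tab$op[idx]
  # strip boundary gap columns: an alignment must start and end aligned
  first <- match(TRUE, ops %in% c("=", "X"))
  if (is.na(first)) return(NULL)
  last <- length(ops) + 1L - match(TRUE, rev(ops) %in% c("=", "X"))
  idx <- idx[first:last]
  ops <- tab$op[idx]
  cons_read <- tab$op[idx] %in% c("=", "X", "I")
  cons_ref <- tab$op[idx] %in% c("=", "X", "D")
  new_alo <- ivl[1] + min(tab$read_off[idx][cons_read])
  new_ahi <- ivl[1] + max(tab$read_off[idx][cons_read]) + 1L
  new_fs <- a$ref_start + min(tab$ref_off[idx][cons_ref])
  new_fe <- a$ref_start + max(tab$ref_off[idx][cons_ref]) + 1L
  out <- a
  if (a$strand == "+") {
    out$read_start <- new_alo; out$read_end <- new_ahi
  } else {
    out$read_start <- read_len - new_ahi; out$read_end <- read_len - new_alo
  }
  out$ref_start <- new_fs; out$ref_end <- new_fe
  out$cigar <- ops_to_cigar(ops)
  st <- alignment_stats(out$cigar, params)
  out$score <- st$score
  out$n_match <- st$n_match
  out$n_mismatch <- st$n_mismatch
  out$n_gapcols <- st$n_gapcols
  out$identity <- st$identity
  out
}

#' Resolve the overlap between two alignments by an optimal cut point
#'
#' Evaluates every cut point `c` in the overlap (inclusive of both ends),
#' trimming `a` to end at `c` and `b` to start at `c`, and returns the pair
#' maximizing the total [bonus_score()]; ties take the smallest cut.
#'
#' @param a,b Single alignment rows of the same read with
#'   `a$read_start < b$read_start`.
#' @param ref A [gene_reference()].
#' @param read_len Read length.
#' @param params An [align_params()] list.
#' @return A list with elements `a`, `b` (either may be `NULL` if trimmed
#'   away) and `cut` (`NA` when the pair did not overlap).
#' @export
resolve_overlap_pair <- function(a, b, ref, read_len,
                                 params = align_params()) {
  stopifnot(a$read_start < b$read_start)
  if (b$read_start >= a$read_end) return(list(a = a, b = b, cut = NA_integer_))
  cuts <- seq.int(b$read_start, a$read_end)
  best <- NULL
  best_total <- -Inf
  best_cut <- NA_integer_
  for (cc in cuts) {
    ta <- trim_alignment(a, 0L, cc, read_len, params)
    tb <- trim_alignment(b, cc, read_len, read_len, params)
    total <- (if (is.null(ta)) 0L else bonus_score(ta, ref, params)) +
      (if (is.null(tb)) 0L else bonus_score(tb, ref, params))
    if (is.null(ta) && is.null(tb)) total <- -Inf
    if (total > best_total) {
      best_total <- total
      best <- list(a = ta, b = tb)
      best_cut <- cc
    }
  }
  c(best, list(cut = best_cut))
}

#' Remove all read-coordinate overlaps from an alignment set
#'
#' Applies [resolve_overlap_pair()] to consecutive overlapping members from
#' left to right on the read. Co-optimal multi-hit siblings (identical read
#' intervals) form one unit and are trimmed identically; a member trimmed to
#' fewer than one aligned base is dropped with a message.
#'
#' @param set An alignment set (tibble) for one read, post filtering.
#' @param ref A [gene_reference()].
#' @param read_len Read length.
#' @param params An [align_params()] list.
#' @return The trimmed set: pairwise non-overlapping on the read except for
#'   identical-interval siblings.
#' @export
resolve_overlaps <- function(set, ref, read_len, params = align_params()) {
  if (nrow(set) < 2) return(set)
  set <- arrange(set, .data$read_start, .data$read_end, .data$ref_start)
  key <- paste(set$score, set$read_start, set$read_end, sep = ":")
  units <- lapply(unique(key), function(k) which(key == k))
  units <- units[order(vapply(units, function(u) set$read_start[u[1]],
                              numeric(1)))]
  rows <- lapply(seq_len(nrow(set)), function(i) set[i, ])
  for (t in seq_len(length(units) - 1)) {
    u1 <- units[[t]]; u2 <- units[[t + 1]]
    r1 <- rows[[u1[1]]]; r2 <- rows[[u2[1]]]
    if (is.null(r1) || is.null(r2)) next
    if (r2$read_start >= r1$read_end) next
    res <- resolve_overlap_pair(r1, r2, ref, read_len, params)
    lo1 <- if (is.null(res$a)) NULL else c(res$a$read_start, res$a$read_end)
    lo2 <- if (is.null(res$b)) NULL else c(res$b$read_start, res$b$read_end)
    retrim <- function(i, lo) {
      if (is.null(rows[[i]])) return(invisible())
      new <- if (is.null(lo)) NULL else
        trim_alignment(rows[[i]], lo[1], lo[2], read_len, params)
      rows[i] <<- list(new) # not [[<-: assigning NULL must keep the slot
      if (is.null(new)) {
        message("alignment trimmed away during overlap resolution")
      }
    }
    for (i in u1) retrim(i, lo1)
    for (i in u2) retrim(i, lo2)
  }
  kept <- bind_rows(rows[!vapply(rows, is.null, logical(1))])
  if (nrow(kept) == 0) return(set[0, ])
  arrange(kept, .data$read_start, .data$ref_start)
}
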
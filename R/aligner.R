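# Multi-hit local alignment of one read against the whole locus.
#
# The aligner seeds on maximal exact matches (no uniqueness filter, so every
# copy of a repeated segment is hit), chains colinear anchors whose read and
# reference gaps are both <= breaklen, joins consecutive anchors by global DP
# over the gap sequences, and extends chain ends within a breaklen-bounded
# window. Chains are extracted best-first by true alignment score, so a merge
# across a gap is only reported when it beats its own sub-chains; when end
# extension changes a chain, both the extended and the bare variant are
# reported and the downstream greedy selection arbitrates.

empty_alignments <- function() {
  tibble(read_id = character(), read_start = integer(), read_end = integer(),
         ref_start = integer(), ref_end = integer(), strand = character(),
         score = integer(), n_match = integer(), n_mismatch = integer(),
         n_gapcols = integer(), identity = numeric(), cigar = character(),
         provenance = character())
}

#' Find all maximal exact-match anchors of a read on the locus
#'
#' Every maximal exact match of length >= `min_anchor` on either strand is
#' returned, including all copies of repeated reference sequence (no
#' uniqueness filter). Non-ACGT bases never match, so a read of Ns yields an
#' empty result.
#'
#' @param read Read sequence (character scalar).
#' @param ref A [gene_reference()].
#' @param params An [align_params()] list.
#' @return A tibble with `read_start`, `read_end` (forward read coordinates,
#'   0-based half-open), `ref_start`, `ref_end`, `strand`, `length`.
#' @export
find_anchors <- function(read, ref, params = align_params()) {
  read <- toupper(read)
  stopifnot(nchar(read) >= params$min_anchor)
  idx <- reference_index(ref, params$min_anchor)
  fw <- cpp_maximal_anchors(read, idx)
  rc <- cpp_maximal_anchors(revcomp(read), idx)
  n <- nchar(read)
  col <- function(m, i) as.integer(unname(m[, i]))
  out <- bind_rows(
    tibble(read_start = col(fw, 1), ref_start = col(fw, 2),
           length = col(fw, 3), strand = rep("+", nrow(fw))),
    tibble(read_start = n - (col(rc, 1) + col(rc, 3)), ref_start = col(rc, 2),
           length = col(rc, 3), strand = rep("-", nrow(rc)))
  )
  out$read_end <- out$read_start + out$length
  out$ref_end <- out$ref_start + out$length
  arrange(
    select(out, "read_start", "read_end", "ref_start", "ref_end", "strand",
           "length"),
    .data$read_start, .data$ref_start, .data$strand)
}

#' Align a read to the whole locus
#'
#' Produces all candidate local alignments on both strands with score >=
#' `min_report_score`, sorted by score (descending). Alignments to repeated
#' reference regions are all reported.
#'
#' @param read Read sequence (character scalar).
#' @param ref A [gene_reference()].
#' @param params An [align_params()] list.
#' @param read_id Read identifier carried into the result.
#' @param breaklen Override of `params$breaklen` (used for relaxed
#'   realignment).
#' @return A tibble of alignments with columns `read_id`, `read_start`,
#'   `read_end`, `ref_start`, `ref_end` (0-based half-open), `strand`,
#'   `score`, `n_match`, `n_mismatch`, `n_gapcols`, `identity`, `cigar`,
#'   `provenance`. `read_start`/`read_end` are forward read coordinates; for
#'   minus-strand rows the CIGAR describes the reverse-complemented read
#'   along the reference.
#' @export
align_read <- function(read, ref, params = align_params(), read_id = "read",
                       breaklen = NULL) {
  read <- toupper(read)
  breaklen <- as.integer(breaklen %||% params$breaklen)
  n <- nchar(read)
  idx <- reference_index(ref, params$min_anchor)
  res <- list()
  fw <- cpp_align_read(read, idx, breaklen,
                       params$match, params$mismatch, params$gap_open,
                       params$gap_extend, params$min_report_score)
  if (nrow(fw) > 0) {
    fw$strand <- "+"
    res[[1]] <- fw
  }
  rc <- cpp_align_read(revcomp(read), idx,
                       breaklen, params$match, params$mismatch,
                       params$gap_open, params$gap_extend,
                       params$min_report_score)
  if (nrow(rc) > 0) {
    rc$strand <- "-"
    tmp <- rc$read_start
    rc$read_start <- n - rc$read_end
    rc$read_end <- n - tmp
    res[[length(res) + 1]] <- rc
  }
  if (length(res) == 0) return(empty_alignments())
  out <- as_tibble(bind_rows(res))
  out$read_id <- read_id
  out$identity <- out$n_match / (out$n_match + out$n_mismatch + out$n_gapcols)
  out$provenance <- "initial"
  out <- out[!duplicated(out[, c("read_start", "read_end", "ref_start",
                                 "ref_end", "strand")]), ]
  arrange(
    select(out, "read_id", "read_start", "read_end", "ref_start", "ref_end",
           "strand", "score", "n_match", "n_mismatch", "n_gapcols",
           "identity", "cigar", "provenance"),
    desc(.data$score), .data$read_start, .data$ref_start, .data$strand)
}

#' Import alignments produced by an external aligner
#'
#' Adapter for substituting a different aligner: reads a TSV with columns
#' `read_id`, `read_start`, `read_end`, `ref_start`, `ref_end` (0-based
#' half-open, forward read coordinates), `strand`, `n_match`, `n_mismatch`,
#' `n_gapcols` and optionally `cigar`. Score and identity are derived under
#' the package's scoring scheme; rows without a CIGAR get `NA` there and
#' cannot be trimmed, but pass through selection and filtering.
#'
#' @param path TSV file path (header row required).
#' @param params An [align_params()] list used to score the rows.
#' @return An alignment tibble as produced by [align_read()].
#' @export
read_external_alignments <- function(path, params = align_params()) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("read_id", "read_start", "read_end", "ref_start", "ref_end",
            "strand", "n_match", "n_mismatch", "n_gapcols")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    stop("external alignment TSV lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!"cigar" %in% names(x)) x$cigar <- NA_character_
  x$score <- vapply(seq_len(nrow(x)), function(i) {
    if (!is.na(x$cigar[i])) {
      alignment_stats(x$cigar[i], params)$score
    } else {
      # approximate: gap columns charged as one run
      as.integer(x$n_match[i] * params$match +
                   x$n_mismatch[i] * params$mismatch +
                   (x$n_gapcols[i] > 0) * params$gap_open +
                   x$n_gapcols[i] * params$gap_extend)
    }
  }, integer(1))
  x$identity <- x$n_match / (x$n_match + x$n_mismatch + x$n_gapcols)
  x$provenance <- "external"
  arrange(as_tibble(x[, names(empty_alignments())]),
          desc(.data$score), .data$read_start, .data$ref_start, .data$strand)
}

# memoised k-mer index of the locus; rebuilt when the anchor length changes
# or after (de)serialisation invalidated the external pointer
reference_index <- function(ref, k) {
  cache <- ref$cache
  if (is.null(cache)) {
    # reference built without a cache environment (e.g. old object): no memo
    return(cpp_build_index(ref$sequence, as.integer(k)))
  }
  idx <- cache$index
  if (is.null(idx) || !cpp_index_ok(idx, ref$sequence, as.integer(k))) {
    idx <- cpp_build_index(ref$sequence, as.integer(k))
    cache$index <- idx
  }
  idx
}
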
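#' Alignment parameters
#'
#' Parameters controlling anchoring, chaining and scoring. The `breaklen`
#' parameter bounds both the gap bridged when chaining anchors into one
#' alignment and how far an alignment may be extended past its last anchor;
#' `relaxed_breaklen` is the value used when a read with multiple surviving V
#' annotations is realigned (see [resolve_multiple_v()]).
#'
#' @param min_anchor Minimum exact-match anchor length in nt (>= 8).
#' @param breaklen Maximum read/reference gap (nt) bridged when chaining, and
#'   the extension window past a chain end.
#' @param relaxed_breaklen `breaklen` used during realignment; must be >=
#'   `breaklen`.
#' @param match,mismatch,gap_open,gap_extend Integer scoring parameters; a gap
#'   run of length L scores `gap_open + L * gap_extend`.
#' @param min_report_score Minimum score for a reported alignment (the default
#'   equals a 20 nt perfect match).
#' @return A list of class `align_params`.
#' @export
align_params <- function(min_anchor = 20L, breaklen = 200L,
                         relaxed_breaklen = 800L, match = 3L, mismatch = -4L,
                         gap_open = -6L, gap_extend = -2L,
                         min_report_score = 60L) {
  stopifnot(min_anchor >= 8L, relaxed_breaklen >= breaklen, match > 0L,
            mismatch < 0L, gap_open < 0L, gap_extend < 0L)
  structure(list(
    min_anchor = as.integer(min_anchor), breaklen = as.integer(breaklen),
    relaxed_breaklen = as.integer(relaxed_breaklen),
    match = as.integer(match), mismatch = as.integer(mismatch),
    gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
    min_report_score = as.integer(min_report_score)
  ), class = "align_params")
}

#' Annotation-aware filter parameters
#'
#' @param cdr3_min_len Minimum length (nt) for a putative-CDR3 alignment to
#'   survive when its segment is not from a D or J region.
#' @param intergenic_min_len,intergenic_min_identity Alignments to intergenic
#'   sequence shorter than `intergenic_min_len` with identity below
#'   `intergenic_min_identity` are filtered.
#' @param intergenic_rule `"conjunctive"` (default; filter only when both the
#'   length and the identity condition hold) or `"disjunctive"` (filter when
#'   either holds).
#' @param upstream_flag_nt A segment whose reference interval starts at least
#'   this many nt before its dominant region is flagged `extends_upstream`.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(cdr3_min_len = 60L, intergenic_min_len = 40L,
                          intergenic_min_identity = 0.95,
                          intergenic_rule = c("conjunctive", "disjunctive"),
                          upstream_flag_nt = 10L) {
  intergenic_rule <- match.arg(intergenic_rule)
  stopifnot(cdr3_min_len > 0, intergenic_min_len > 0,
            intergenic_min_identity > 0, intergenic_min_identity <= 1)
  structure(list(
    cdr3_min_len = as.integer(cdr3_min_len),
    intergenic_min_len = as.integer(intergenic_min_len),
    intergenic_min_identity = intergenic_min_identity,
    intergenic_rule = intergenic_rule,
    upstream_flag_nt = as.integer(upstream_flag_nt)
  ), class = "filter_params")
}
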
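# Annotation-aware filtering of an optimal alignment set, in fixed order:
# exon-consistency resolution -> putative-CDR3 flag + filter -> intergenic
# filter -> relaxed realignment of reads with multiple surviving V
# annotations. Filters only ever remove alignments; the realignment step may
# replace the set with a rebuilt one in which two alignments have merged.

# dominant region info per member, as extra columns
member_labels <- function(set, ref) {
  if (nrow(set) == 0) {
    set$dom_kind <- character()
    set$dom_label <- character()
    set$dom_gene <- character()
    set$dom_genes <- list()
    set$dom_region_start <- integer()
    set$dom_pseudogene <- logical()
    return(set)
  }
  info <- lapply(seq_len(nrow(set)), function(i) {
    dominant_region(ref, set$ref_start[i], set$ref_end[i])
  })
  set$dom_kind <- vapply(info, `[[`, character(1), "kind")
  set$dom_label <- vapply(info, `[[`, character(1), "label")
  set$dom_gene <- vapply(info, `[[`, character(1), "name")
  set$dom_genes <- lapply(info, `[[`, "genes")
  set$dom_region_start <- vapply(info, function(x) {
    as.integer(x$region_start %||% NA_integer_)
  }, integer(1))
  set$dom_pseudogene <- vapply(info, `[[`, logical(1), "pseudogene")
  set
}

# co-optimal group key: equal score and identical read interval
cooptimal_key <- function(set) {
  paste(set$score, set$read_start, set$read_end, sep = ":")
}

#' Resolve co-optimal V-exon hits using the partner exon
#'
#' When one read segment aligns equally well to the same exon of several V
#' genes, and another member of the set aligns to the partner exon of a subset
#' of those genes, only the supported co-optimal alignments are kept.
#'
#' @param set An optimal alignment set (tibble) for one read.
#' @param ref A [gene_reference()].
#' @return The filtered set.
#' @export
filter_by_exon_consistency <- function(set, ref) {
  if (nrow(set) < 2) return(set)
  lab <- member_labels(set, ref)
  key <- cooptimal_key(lab)
  drop <- rep(FALSE, nrow(lab))
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2) next
    kinds <- lab$dom_kind[idx]
    for (exon in c("V_EXON1", "V_EXON2")) {
      grp <- idx[kinds == exon]
      if (length(grp) < 2) next
      genes <- lab$dom_gene[grp]
      if (length(unique(genes)) < 2) next
      partner <- setdiff(c("V_EXON1", "V_EXON2"), exon)
      support <- unique(unlist(
        lab$dom_genes[lab$dom_kind == partner & !(seq_len(nrow(lab)) %in% grp)]
      ))
      supported <- genes %in% support
      if (any(supported) && !all(supported)) drop[grp[!supported]] <- TRUE
    }
  }
  set[!drop, ]
}

# members ordered along the transcript: ascending read_start for plus-strand
# reads, descending for minus-strand (so "left neighbour" is 5' in the mRNA)
transcript_order <- function(set) {
  minus <- sum(set$strand == "-") > nrow(set) / 2
  o <- order(set$read_start, set$ref_start)
  if (minus) rev(o) else o
}

#' Flag putative-CDR3 alignments
#'
#' A member is flagged when its immediate neighbours among the surviving
#' members of the set are a V second-exon alignment on the 5' side and a J
#' alignment on the 3' side of the transcript (mirrored for minus-strand
#' reads). Gaps between neighbours are permitted: junction N-additions make
#' exact abutment impossible.
#'
#' @param set An optimal alignment set for one read.
#' @param ref A [gene_reference()].
#' @return A logical vector flagging the members of `set`.
#' @export
identify_putative_cdr3 <- function(set, ref) {
  flag <- rep(FALSE, nrow(set))
  if (nrow(set) < 3) return(flag)
  lab <- member_labels(set, ref)
  ord <- transcript_order(lab)
  kinds <- lab$dom_kind[ord]
  labels <- lab$dom_label[ord]
  for (p in seq_along(ord)[-c(1, length(ord))]) {
    if (kinds[p - 1] == "V_EXON2" && labels[p + 1] == "J") {
      flag[ord[p]] <- TRUE
    }
  }
  flag
}

#' Filter flagged putative-CDR3 alignments
#'
#' A flagged alignment survives if its segment is from a D or J region, or the
#' alignment is long (read-interval length >= `cdr3_min_len`); otherwise it is
#' removed.
#'
#' @param set An optimal alignment set for one read.
#' @param flagged Logical vector as returned by [identify_putative_cdr3()].
#' @param params A [filter_params()] list.
#' @param ref A [gene_reference()].
#' @return The filtered set.
#' @export
filter_cdr3_alignments <- function(set, flagged, params = filter_params(),
                                   ref) {
  if (!any(flagged)) return(set)
  lab <- member_labels(set, ref)
  len <- set$read_end - set$read_start
  keep <- !flagged | lab$dom_label %in% c("D", "J") | len >= params$cdr3_min_len
  set[keep, ]
}

#' Filter short, inferior intergenic alignments
#'
#' Removes members whose dominant label is intergenic and which are short
#' (< `intergenic_min_len`) and of low identity (< `intergenic_min_identity`).
#' Under `intergenic_rule = "disjunctive"` either condition alone suffices.
#'
#' @param set An optimal alignment set for one read.
#' @param params A [filter_params()] list.
#' @param ref A [gene_reference()].
#' @return The filtered set.
#' @export
filter_intergenic_alignments <- function(set, params = filter_params(), ref) {
  if (nrow(set) == 0) return(set)
  lab <- member_labels(set, ref)
  short <- (set$read_end - set$read_start) < params$intergenic_min_len
  inferior <- set$identity < params$intergenic_min_identity
  bad <- if (params$intergenic_rule == "conjunctive") {
    short & inferior
  } else {
    short | inferior
  }
  set[!(lab$dom_label == "INTERGENIC" & bad), ]
}

# distinct V genes annotated by co-optimal member groups
cooptimal_v_genes <- function(set, ref) {
  lab <- member_labels(set, ref)
  key <- cooptimal_key(lab)
  out <- list()
  for (k in unique(key)) {
    idx <- which(key == k & lab$dom_label == "V")
    genes <- unique(lab$dom_gene[idx])
    if (length(genes) > 1) {
      out[[length(out) + 1]] <- list(
        idx = idx, genes = genes,
        read_start = min(lab$read_start[idx]),
        read_end = max(lab$read_end[idx]))
    }
  }
  out
}

# selection + the annotation-aware filters (without the realignment step)
apply_filter_stack <- function(alignments, ref, align_par, filter_par,
                               threshold = 0.5) {
  set <- optimal_alignment_set(alignments, threshold)
  set <- filter_by_exon_consistency(set, ref)
  flagged <- identify_putative_cdr3(set, ref)
  set$putative_cdr3 <- flagged
  set <- filter_cdr3_alignments(set, flagged, filter_par, ref)
  filter_intergenic_alignments(set, filter_par, ref)
}

#' Resolve multiple V annotations by relaxed realignment
#'
#' When co-optimal alignments annotate more than one V gene, the read is
#' realigned with `relaxed_breaklen`, allowing alignments to extend further
#' outward, and selection plus the annotation-aware filters are rerun. If,
#' among the realigned candidates overlapping the ambiguous segment, exactly
#' one V gene attains a strictly higher score than all others, the rebuilt set
#' (keeping that alignment) replaces the original; otherwise the ambiguity is
#' retained and both V names are reported downstream.
#'
#' @param set An optimal, filtered alignment set for one read.
#' @param read The read sequence.
#' @param ref A [gene_reference()].
#' @param params An [align_params()] list (supplies `relaxed_breaklen`).
#' @param filter_par A [filter_params()] list.
#' @param threshold Conflict threshold for selection.
#' @return The (possibly rebuilt) alignment set.
#' @export
resolve_multiple_v <- function(set, read, ref, params = align_params(),
                               filter_par = filter_params(), threshold = 0.5) {
  amb <- cooptimal_v_genes(set, ref)
  if (length(amb) == 0) return(set)
  relaxed <- align_read(read, ref, params, read_id = set$read_id[1],
                        breaklen = params$relaxed_breaklen)
  if (nrow(relaxed) == 0) return(set)
  rebuilt <- apply_filter_stack(relaxed, ref, params, filter_par, threshold)
  rebuilt$provenance <- "realignment"
  lab <- member_labels(rebuilt, ref)
  resolved <- TRUE
  for (grp in amb) {
    cand <- which(lab$dom_label == "V" &
                    lab$read_start < grp$read_end &
                    lab$read_end > grp$read_start)
    if (length(cand) == 0) { resolved <- FALSE; next }
    best <- max(rebuilt$score[cand])
    best_genes <- unique(lab$dom_gene[cand][rebuilt$score[cand] == best])
    if (length(best_genes) != 1) resolved <- FALSE
  }
  if (resolved) rebuilt else set
}
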
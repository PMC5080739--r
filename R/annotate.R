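# From trimmed alignments to biology: segment labels, regularity class, CDR3.
#
# Each surviving alignment (or group of co-optimal multi-hit siblings) becomes
# one segment labelled V, D, J, C or INTERGENIC by the dominant region kind of
# its reference interval. The regularity class follows the read taxonomy of
# RACE repertoire data: a read with both a V and a J segment is regular;
# non-regular reads are subclassified by what sits immediately 5' of the J
# segment in the transcript (genomic upstream extension, a D, a C, an
# intergenic segment, or another J), or by containing only
# intergenic/C-only/V-only material.

REGULARITY_CLASSES <- c("REGULAR", "J_NO_V", "DJ", "J_C", "J_J",
                        "J_INTERGENIC", "INTERGENIC_ONLY", "C_ONLY", "V_ONLY",
                        "OTHER")

#' Convert a final alignment set into segment annotations
#'
#' Co-optimal siblings (identical read interval and score) merge into one
#' segment flagged `multi_hit_ambiguous`, carrying all their gene names. A
#' segment whose reference interval starts well upstream of its dominant
#' region is flagged `extends_upstream`.
#'
#' @param set A trimmed alignment set for one read.
#' @param ref A [gene_reference()].
#' @param params A [filter_params()] list (supplies the upstream-extension
#'   flag distance).
#' @return A tibble of segments ordered by read position, with columns
#'   `read_id`, `label`, `kind`, `gene` (comma-joined names in locus order, or
#'   `intergenic:start-end`), `genes` (list column), coordinates, `strand`,
#'   `score`, `identity`, `extends_upstream`, `covers_pseudogene`,
#'   `multi_hit_ambiguous`, `putative_cdr3`, `cigar`.
#' @export
annotate_segments <- function(set, ref, params = filter_params()) {
  out <- tibble(read_id = character(), label = character(),
                kind = character(), gene = character(), genes = list(),
                read_start = integer(), read_end = integer(),
                ref_start = integer(), ref_end = integer(),
                strand = character(), score = integer(), identity = numeric(),
                extends_upstream = logical(), covers_pseudogene = logical(),
                multi_hit_ambiguous = logical(), putative_cdr3 = logical(),
                cigar = character())
  if (nrow(set) == 0) return(out)
  if (!"putative_cdr3" %in% names(set)) set$putative_cdr3 <- FALSE
  lab <- member_labels(set, ref)
  key <- cooptimal_key(lab)
  segs <- lapply(unique(key), function(k) {
    grp <- lab[key == k, ]
    grp <- arrange(grp, .data$ref_start)
    rep_row <- grp[1, ]
    genes <- unique(unlist(grp$dom_genes[grp$dom_label == rep_row$dom_label]))
    gene <- if (rep_row$dom_label == "INTERGENIC") {
      sprintf("intergenic:%d-%d", rep_row$ref_start + 1L, rep_row$ref_end)
    } else {
      paste(genes, collapse = ",")
    }
    upstream <- !is.na(rep_row$dom_region_start) &&
      rep_row$ref_start <= rep_row$dom_region_start - params$upstream_flag_nt
    tibble(
      read_id = rep_row$read_id, label = rep_row$dom_label,
      kind = rep_row$dom_kind, gene = gene, genes = list(genes),
      read_start = rep_row$read_start, read_end = rep_row$read_end,
      ref_start = rep_row$ref_start, ref_end = rep_row$ref_end,
      strand = rep_row$strand, score = rep_row$score,
      identity = rep_row$identity, extends_upstream = upstream,
      covers_pseudogene = any(grp$dom_pseudogene),
      multi_hit_ambiguous = length(unique(grp$dom_gene)) > 1,
      putative_cdr3 = any(grp$putative_cdr3), cigar = rep_row$cigar
    )
  })
  arrange(bind_rows(segs), .data$read_start, .data$ref_start)
}

#' Classify a read's recombination pattern
#'
#' A read with at least one V and one J segment is `REGULAR`. A read with a J
#' but no V is subclassified by the segment immediately 5' of a J segment in
#' the transcript: a D gives `DJ`, a C gives `J_C`, a different J gives `J_J`,
#' an intergenic segment gives `J_INTERGENIC`; a J with no 5' partner (the
#' alignment typically extends into the genomic upstream of the J region)
#' gives `J_NO_V`. Reads without a J are `INTERGENIC_ONLY`, `C_ONLY` or
#' `V_ONLY` when made only of those labels (V may be accompanied by C), and
#' `OTHER` otherwise (including empty segment lists).
#'
#' @param segments A segment tibble from [annotate_segments()].
#' @return A single class string; see `REGULARITY_CLASSES`.
#' @export
classify_read <- function(segments) {
  if (nrow(segments) == 0) return("OTHER")
  labels <- segments$label
  if (any(labels == "V") && any(labels == "J")) return("REGULAR")
  if (any(labels == "J")) {
    ord <- transcript_order(segments)
    lab5 <- labels[ord]
    gene5 <- segments$gene[ord]
    pred <- character()
    for (p in which(lab5 == "J")) {
      if (p == 1) next
      if (lab5[p - 1] == "J" && gene5[p - 1] != gene5[p]) {
        pred <- c(pred, "J")
      } else if (lab5[p - 1] != "J") {
        pred <- c(pred, lab5[p - 1])
      }
    }
    if ("D" %in% pred) return("DJ")
    if ("C" %in% pred) return("J_C")
    if ("J" %in% pred) return("J_J")
    if ("INTERGENIC" %in% pred) return("J_INTERGENIC")
    return("J_NO_V")
  }
  if (all(labels == "INTERGENIC")) return("INTERGENIC_ONLY")
  if (all(labels == "C")) return("C_ONLY")
  if (any(labels == "V") && all(labels %in% c("V", "C"))) return("V_ONLY")
  "OTHER"
}

# map a reference position through an alignment trace to a strand-adjusted
# read position; toward = "right"/"left" resolves positions falling in a
# read-gap column toward the CDR3 junction
map_ref_to_read <- function(row, pos, read_len, toward = "right") {
  tab <- cigar_table(row$cigar)
  off <- pos - row$ref_start
  consuming <- tab$op %in% c("=", "X")
  hit <- which(tab$ref_off == off & tab$op %in% c("=", "X", "D"))
  if (length(hit) == 0) return(NULL)
  hit <- hit[1]
  in_gap <- tab$op[hit] == "D"
  if (in_gap) {
    cand <- if (toward == "right") {
      which(consuming & seq_along(consuming) > hit)
    } else {
      which(consuming & seq_along(consuming) < hit)
    }
    if (length(cand) == 0) return(NULL)
    hit <- if (toward == "right") cand[1] else cand[length(cand)]
  }
  ivl <- adjusted_read_interval(row, read_len)
  list(adj_pos = ivl[1] + tab$read_off[hit], in_gap = in_gap)
}

#' Extract the CDR3 junction from annotated segments
#'
#' Searches for a V segment covering its gene's conserved 2nd-CYS anchor and
#' a downstream J segment (same strand) covering its J-PHE/J-TRP anchor, maps
#' both anchors through the alignment traces to read positions, and reports
#' the anchor-inclusive CDR3 (first base of the Cys codon through last base
#' of the Phe/Trp codon) together with the anchor-exclusive IMGT-style
#' interval. The sequence is reported in mRNA sense; the interval on forward
#' read coordinates.
#'
#' @param segments A segment tibble from [annotate_segments()].
#' @param read The read sequence.
#' @param ref A [gene_reference()].
#' @return A one-row tibble, or `NULL` when no valid V/J anchor pair exists.
#' @export
extract_cdr3 <- function(segments, read, ref) {
  read_len <- nchar(read)
  vsegs <- segments[segments$label == "V", ]
  jsegs <- segments[segments$label == "J", ]
  if (nrow(vsegs) == 0 || nrow(jsegs) == 0) return(NULL)
  anch <- ref$anchors
  for (vi in seq_len(nrow(vsegs))) {
    vseg <- vsegs[vi, ]
    vgenes <- vseg$genes[[1]]
    vanch <- anch[anch$type == "V" & anch$gene %in% vgenes, ]
    vanch <- vanch[vanch$pos >= vseg$ref_start & vanch$pos < vseg$ref_end, ]
    if (nrow(vanch) == 0) next
    vmap <- map_ref_to_read(vseg, vanch$pos[1], read_len, toward = "right")
    if (is.null(vmap)) next
    for (ji in seq_len(nrow(jsegs))) {
      jseg <- jsegs[ji, ]
      if (jseg$strand != vseg$strand) next
      jgenes <- jseg$genes[[1]]
      janch <- anch[anch$type == "J" & anch$gene %in% jgenes, ]
      janch <- janch[janch$pos >= jseg$ref_start & janch$pos < jseg$ref_end, ]
      if (nrow(janch) == 0) next
      jmap <- map_ref_to_read(jseg, janch$pos[nrow(janch)], read_len,
                              toward = "left")
      if (is.null(jmap)) next
      v_adj <- vmap$adj_pos
      j_adj <- jmap$adj_pos
      if (j_adj <= v_adj) next
      sense <- if (vseg$strand == "+") read else revcomp(read)
      nt <- substr(sense, v_adj + 1L, j_adj + 1L)
      len <- nchar(nt)
      aa_len <- 3L * (len %/% 3L)
      aa <- if (aa_len >= 3) translate_nt(substr(nt, 1, aa_len)) else ""
      fwd <- if (vseg$strand == "+") {
        c(v_adj, j_adj + 1L)
      } else {
        c(read_len - (j_adj + 1L), read_len - v_adj)
      }
      return(tibble(
        read_id = vseg$read_id,
        v_gene = paste(sort(vgenes), collapse = ","),
        j_gene = paste(sort(jgenes), collapse = ","),
        read_start = fwd[1], read_end = fwd[2],
        imgt_start = fwd[1] + 3L, imgt_end = fwd[2] - 3L,
        nt = nt, aa = aa,
        in_frame = len %% 3L == 0L,
        has_stop = grepl("\\*", aa),
        anchor_in_gap = vmap$in_gap || jmap$in_gap
      ))
    }
  }
  NULL
}

# translate in-frame nucleotides; ambiguous codons give "X"
translate_nt <- function(nt) {
  tbl <- .vdj_cache$genetic_code
  if (is.null(tbl)) {
    tbl <- Biostrings::GENETIC_CODE
    .vdj_cache$genetic_code <- tbl
  }
  n <- nchar(nt)
  codons <- substring(nt, seq(1, n - 2, 3), seq(3, n, 3))
  aa <- unname(tbl[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

normalize_calls <- function(x) {
  lapply(x, function(s) {
    if (length(s) == 0 || is.na(s) || !nzchar(s)) return(character())
    sort(unique(trimws(strsplit(s, ",")[[1]])))
  })
}

#' Compare V/J annotations between two runs or tools
#'
#' Per-read categories over the shared read set: `identical` (same V and J
#' call sets), `extra` (the second input made additional V or J calls),
#' `missing` (it missed some), `distinct` (disagreeing calls), and `non_vj`
#' (the second input has no V and no J call for a read the first annotated).
#' Reads present in only one input are tallied as `unannotated`.
#'
#' @param a,b Data frames with columns `read_id`, `v_calls`, `j_calls`
#'   (comma-joined gene names, `""` or `NA` for none), e.g. the `annotations`
#'   element of a [run_pipeline()] result.
#' @return A list with `reads` (per-read tibble: `read_id`, `category`) and
#'   `tally` (category counts, including `unannotated`).
#' @export
compare_annotations <- function(a, b) {
  a_ids <- a$read_id
  b_ids <- b$read_id
  common <- intersect(a_ids, b_ids)
  av <- normalize_calls(a$v_calls[match(common, a_ids)])
  aj <- normalize_calls(a$j_calls[match(common, a_ids)])
  bv <- normalize_calls(b$v_calls[match(common, b_ids)])
  bj <- normalize_calls(b$j_calls[match(common, b_ids)])
  cat1 <- vapply(seq_along(common), function(i) {
    if (setequal(av[[i]], bv[[i]]) && setequal(aj[[i]], bj[[i]])) {
      return("identical")
    }
    if (length(bv[[i]]) + length(bj[[i]]) == 0 &&
        length(av[[i]]) + length(aj[[i]]) > 0) {
      return("non_vj")
    }
    if (all(av[[i]] %in% bv[[i]]) && all(aj[[i]] %in% bj[[i]])) {
      return("extra")
    }
    if (all(bv[[i]] %in% av[[i]]) && all(bj[[i]] %in% aj[[i]])) {
      return("missing")
    }
    "distinct"
  }, character(1))
  reads <- tibble(read_id = common, category = cat1)
  cats <- c("identical", "extra", "missing", "distinct", "non_vj")
  tally <- tibble(
    category = c(cats, "unannotated"),
    n = c(unname(vapply(cats, function(k) sum(cat1 == k), integer(1))),
          length(setdiff(union(a_ids, b_ids), common)))
  )
  list(reads = reads, tally = tally)
}
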
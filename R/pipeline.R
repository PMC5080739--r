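# End-to-end orchestration: length prefilter -> alignment -> greedy optimal
# set -> annotation-aware filters -> relaxed realignment for multi-V reads ->
# overlap trimming -> segment annotation, classification and CDR3 extraction.
# Reads are processed independently, so a dataset may be sharded by read and
# the per-read records concatenated.

#' Annotate a single read
#'
#' Runs the full per-read pipeline (no length prefilter) and returns the
#' pieces; [run_pipeline()] is the batch driver.
#'
#' @param read Read sequence.
#' @param ref A [gene_reference()].
#' @param read_id Read identifier.
#' @param align_par An [align_params()] list.
#' @param filter_par A [filter_params()] list.
#' @param threshold Overlap-conflict threshold for selection.
#' @return A list with `annotation` (one-row tibble: `read_id`, `class`,
#'   `v_calls`, `j_calls`, `n_segments`, `cdr3_nt`, `cdr3_aa`), `segments`,
#'   and `cdr3` (`NULL` when absent).
#' @export
annotate_read <- function(read, ref, read_id = "read",
                          align_par = align_params(),
                          filter_par = filter_params(), threshold = 0.5) {
  read <- toupper(read)
  aln <- align_read(read, ref, align_par, read_id = read_id)
  set <- apply_filter_stack(aln, ref, align_par, filter_par, threshold)
  set <- resolve_multiple_v(set, read, ref, align_par, filter_par, threshold)
  set <- resolve_overlaps(set, ref, nchar(read), align_par)
  segments <- annotate_segments(set, ref, filter_par)
  cls <- classify_read(segments)
  cdr3 <- extract_cdr3(segments, read, ref)
  vs <- sort(unique(unlist(segments$genes[segments$label == "V"])))
  js <- sort(unique(unlist(segments$genes[segments$label == "J"])))
  annotation <- tibble(
    read_id = read_id, class = cls,
    v_calls = paste(vs, collapse = ","), j_calls = paste(js, collapse = ","),
    n_segments = nrow(segments),
    cdr3_nt = if (is.null(cdr3)) NA_character_ else cdr3$nt,
    cdr3_aa = if (is.null(cdr3)) NA_character_ else cdr3$aa
  )
  list(annotation = annotation, segments = segments, cdr3 = cdr3)
}

#' Run the annotation pipeline over a read set
#'
#' Reads shorter than `min_read_len` are counted and skipped (primer-trimmed
#' RACE reads below 100 bp carry too little information to place on the
#' locus). Per-read processing is independent: splitting the input, running
#' shards and concatenating gives identical records.
#'
#' @param reads A tibble with `read_id` and `sequence` columns, or a path to
#'   a FASTA/FASTQ file (qualities are read but unused).
#' @param ref A [gene_reference()].
#' @param align_par An [align_params()] list.
#' @param filter_par A [filter_params()] list.
#' @param min_read_len Minimum read length in nt.
#' @param threshold Overlap-conflict threshold for selection.
#' @return An object of class `vdj_run`: a list with `annotations` (one row
#'   per processed read), `segments`, `cdr3`, `summary` (see
#'   [summarize_annotations()]), `n_too_short`, and the parameters used.
#' @export
run_pipeline <- function(reads, ref, align_par = align_params(),
                         filter_par = filter_params(), min_read_len = 100L,
                         threshold = 0.5) {
  if (is.character(reads) && length(reads) == 1) {
    reads <- read_fasta_or_fastq(reads)
  }
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  too_short <- nchar(reads$sequence) < min_read_len
  n_too_short <- sum(too_short)
  reads <- reads[!too_short, ]
  if (nrow(reads) == 0) {
    warning("no reads passed the length prefilter")
  }
  res <- lapply(seq_len(nrow(reads)), function(i) {
    annotate_read(reads$sequence[i], ref, read_id = reads$read_id[i],
                  align_par = align_par, filter_par = filter_par,
                  threshold = threshold)
  })
  annotations <- bind_rows(lapply(res, `[[`, "annotation"))
  segments <- bind_rows(lapply(res, `[[`, "segments"))
  cdr3 <- bind_rows(lapply(res, function(x) x$cdr3))
  structure(list(
    annotations = annotations, segments = segments, cdr3 = cdr3,
    summary = summarize_annotations(annotations, segments),
    n_too_short = n_too_short, align_par = align_par,
    filter_par = filter_par, min_read_len = min_read_len,
    threshold = threshold
  ), class = "vdj_run")
}

#' Summarise read annotations
#'
#' Counts and fractions per regularity class, plus the breakdown of what the
#' J segment of J-without-V reads is joined to (its 5' partner: genomic
#' upstream, D, C, intergenic, or another J), mirroring how non-regular RACE
#' reads are reported.
#'
#' @param annotations Annotation tibble (one row per read).
#' @param segments Optional segment tibble (unused, reserved).
#' @return A list with `classes` (tibble: `class`, `n`, `fraction`),
#'   `non_regular_fraction`, and `j_partners` (among reads with a J but no
#'   V).
#' @export
summarize_annotations <- function(annotations, segments = NULL) {
  n <- nrow(annotations)
  if (n == 0) {
    return(list(classes = tibble(class = character(), n = integer(),
                                 fraction = numeric()),
                non_regular_fraction = NA_real_,
                j_partners = tibble(partner = character(), n = integer(),
                                    fraction = numeric())))
  }
  cls <- factor(annotations$class, levels = REGULARITY_CLASSES)
  tab <- table(cls)
  classes <- tibble(class = names(tab), n = as.integer(tab),
                    fraction = as.integer(tab) / n)
  jmap <- c(J_NO_V = "upstream", DJ = "D", J_C = "C",
            J_INTERGENIC = "intergenic", J_J = "J")
  jsub <- annotations$class[annotations$class %in% names(jmap)]
  jp <- table(factor(unname(jmap[jsub]), levels = unname(jmap)))
  j_partners <- tibble(partner = names(jp), n = as.integer(jp),
                       fraction = if (length(jsub) > 0) {
                         as.integer(jp) / length(jsub)
                       } else {
                         rep(NA_real_, length(jp))
                       })
  list(classes = classes,
       non_regular_fraction = mean(annotations$class != "REGULAR"),
       j_partners = j_partners)
}

#' Read a pipeline configuration from a YAML file
#'
#' Every tunable of the pipeline can be given in one YAML file with optional
#' blocks `align`, `filter`, and top-level `min_read_len` / `threshold`;
#' omitted entries take the package defaults.
#'
#' @param path YAML file path.
#' @return A list with `align_par`, `filter_par`, `min_read_len`,
#'   `threshold`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  list(
    align_par = do.call(align_params, y$align %||% list()),
    filter_par = do.call(filter_params, y$filter %||% list()),
    min_read_len = as.integer(y$min_read_len %||% 100L),
    threshold = y$threshold %||% 0.5
  )
}

to_1based <- function(start0) start0 + 1L

#' Write per-read annotations as TSV
#'
#' One row per read with the class, sorted V/J call lists, CDR3 nucleotide
#' and amino-acid sequences, and the segment blocks encoded as
#' `gene:readStart-readEnd:refStart-refEnd:strand:score:identity` with
#' 1-based inclusive coordinates.
#'
#' @param run A `vdj_run` object.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(run, path) {
  seg_block <- function(rid) {
    s <- run$segments[run$segments$read_id == rid, ]
    if (nrow(s) == 0) return("")
    paste(sprintf("%s:%d-%d:%d-%d:%s:%d:%.4f",
                  ifelse(s$label == "INTERGENIC", s$gene, s$gene),
                  to_1based(s$read_start), s$read_end,
                  to_1based(s$ref_start), s$ref_end,
                  s$strand, s$score, s$identity),
          collapse = ";")
  }
  flags_block <- function(rid) {
    s <- run$segments[run$segments$read_id == rid, ]
    f <- c(
      if (any(s$extends_upstream)) "extends_upstream",
      if (any(s$covers_pseudogene)) "covers_pseudogene",
      if (any(s$multi_hit_ambiguous)) "multi_hit_ambiguous"
    )
    paste(f, collapse = ",")
  }
  a <- run$annotations
  out <- data.frame(
    read_id = a$read_id, class = a$class,
    segments = vapply(a$read_id, seg_block, character(1)),
    v_calls = a$v_calls, j_calls = a$j_calls,
    cdr3_nt = a$cdr3_nt, cdr3_aa = a$cdr3_aa,
    flags = vapply(a$read_id, flags_block, character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an annotation TSV
#'
#' @param path A TSV written by [write_annotations()].
#' @return A tibble with at least `read_id`, `v_calls`, `j_calls`.
#' @export
read_annotations <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE,
                              colClasses = "character", quote = ""))
}

#' Write extracted CDR3 segments as FASTA
#'
#' @param run A `vdj_run` object.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_cdr3_fasta <- function(run, path) {
  cd <- run$cdr3
  if (is.null(cd) || nrow(cd) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  lines <- as.vector(rbind(
    sprintf(">%s %s/%s %d-%d", cd$read_id, cd$v_gene, cd$j_gene,
            to_1based(cd$read_start), cd$read_end),
    cd$nt))
  writeLines(lines, path)
  invisible(path)
}
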
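# Whole-locus reference: one nucleotide sequence covering the complete
# receptor gene (V, D, J and C regions plus introns and intergenic DNA), a
# typed region annotation, and the conserved CDR3 anchor codons. Positions are
# 0-based half-open internally; human-readable output is 1-based inclusive.

REGION_KINDS <- c("V_EXON1", "V_EXON2", "D", "J", "C_EXON")

kind_to_label <- function(kind) {
  out <- kind
  out[kind %in% c("V_EXON1", "V_EXON2")] <- "V"
  out[kind == "C_EXON"] <- "C"
  out
}

#' Construct and validate a whole-locus gene reference
#'
#' @param locus_id Identifier of the locus sequence.
#' @param sequence Nucleotide string (A/C/G/T/N) of the whole locus.
#' @param regions A data frame with columns `name`, `kind` (one of `V_EXON1`,
#'   `V_EXON2`, `D`, `J`, `C_EXON`), `start`, `end` (0-based half-open),
#'   `strand`, `pseudogene`. Every V gene must contribute exactly one exon of
#'   each kind, with exon 1 before exon 2. Positions not covered by any region
#'   are implicitly intergenic.
#' @param anchors A data frame with columns `gene`, `type` (`"V"` or `"J"`) and
#'   `pos` (0-based locus position): for a V gene, the first base of the
#'   conserved 2nd-CYS codon (inside its second exon); for a J region, the
#'   last base of the conserved J-PHE/J-TRP codon (inside the J).
#' @return An object of class `gene_reference`.
#' @export
gene_reference <- function(locus_id, sequence, regions, anchors) {
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  regions <- as_tibble(regions)
  anchors <- as_tibble(anchors)
  stopifnot(all(c("name", "kind", "start", "end") %in% names(regions)))
  if (!"strand" %in% names(regions)) regions$strand <- "+"
  if (!"pseudogene" %in% names(regions)) regions$pseudogene <- FALSE
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  regions$pseudogene <- as.logical(regions$pseudogene)

  bad_kind <- setdiff(unique(regions$kind), REGION_KINDS)
  if (length(bad_kind) > 0) {
    stop("unknown region kind(s): ", paste(bad_kind, collapse = ", "))
  }
  if (any(regions$end <= regions$start)) {
    bad <- regions$name[regions$end <= regions$start]
    stop("degenerate region interval (end <= start): ",
         paste(bad, collapse = ", "))
  }
  if (any(regions$start < 0L) || any(regions$end > len)) {
    bad <- regions$name[regions$start < 0L | regions$end > len]
    stop("region outside locus bounds: ", paste(bad, collapse = ", "))
  }
  # same-kind regions must not overlap
  for (k in unique(regions$kind)) {
    rk <- regions[regions$kind == k, ]
    rk <- rk[order(rk$start), ]
    if (nrow(rk) > 1) {
      ov <- which(rk$start[-1] < rk$end[-nrow(rk)])
      if (length(ov) > 0) {
        stop("overlapping regions of kind ", k, ": ", rk$name[ov[1]], " and ",
             rk$name[ov[1] + 1])
      }
    }
  }
  # V genes: exactly one exon of each kind, exon1 before exon2
  vgenes <- unique(regions$name[regions$kind %in% c("V_EXON1", "V_EXON2")])
  for (g in vgenes) {
    e1 <- regions[regions$name == g & regions$kind == "V_EXON1", ]
    e2 <- regions[regions$name == g & regions$kind == "V_EXON2", ]
    if (nrow(e1) != 1 || nrow(e2) != 1) {
      stop("V gene ", g, " must have exactly one exon 1 and one exon 2")
    }
    if (e1$end > e2$start) {
      stop("V gene ", g, ": exon 1 must precede exon 2")
    }
  }
  # anchors inside their regions
  if (nrow(anchors) > 0) {
    stopifnot(all(c("gene", "type", "pos") %in% names(anchors)))
    anchors$pos <- as.integer(anchors$pos)
    for (i in seq_len(nrow(anchors))) {
      an <- anchors[i, ]
      kind <- if (an$type == "V") "V_EXON2" else "J"
      reg <- regions[regions$name == an$gene & regions$kind == kind, ]
      if (nrow(reg) != 1 || an$pos < reg$start || an$pos >= reg$end) {
        stop("anchor for ", an$gene, " (", an$type,
             ") lies outside its region")
      }
    }
  }
  regions <- arrange(regions, .data$start, .data$end)
  # mask of V/D/J positions, used by the exon bonus during trimming (C-region
  # bases deliberately receive no bonus)
  vdj_mask <- logical(len)
  vdj <- regions[regions$kind != "C_EXON", ]
  for (i in seq_len(nrow(vdj))) {
    vdj_mask[(vdj$start[i] + 1):vdj$end[i]] <- TRUE
  }
  structure(list(locus_id = locus_id, sequence = sequence, length = len,
                 regions = regions, anchors = anchors, vdj_mask = vdj_mask,
                 cache = new.env(parent = emptyenv())),
            class = "gene_reference")
}

#' @export
print.gene_reference <- function(x, ...) {
  nk <- table(factor(x$regions$kind, levels = REGION_KINDS))
  cat("<gene_reference> ", x$locus_id, ": ", x$length, " bp\n", sep = "")
  cat("  regions:", paste(names(nk), nk, sep = "=", collapse = " "), "\n")
  cat("  anchors:", sum(x$anchors$type == "V"), "V,",
      sum(x$anchors$type == "J"), "J\n")
  invisible(x)
}

#' Load a gene reference from FASTA + annotation + anchors files
#'
#' The annotation file is BED6 plus two extra columns (`kind`, `pseudogene`),
#' 0-based half-open, with a header line declaring the dialect
#' (`#vdjalign-regions v1`). The anchors file is a TSV with columns `gene`,
#' `type`, `pos` (0-based) and header `#vdjalign-anchors v1`.
#'
#' @param fasta_path FASTA with exactly one locus record.
#' @param annotation_path Region annotation file (see Details).
#' @param anchors_path CDR3 anchors file.
#' @return A validated [gene_reference()].
#' @export
load_reference <- function(fasta_path, annotation_path, anchors_path) {
  ss <- Biostrings::readDNAStringSet(fasta_path)
  if (length(ss) != 1) {
    stop("reference FASTA must contain exactly one locus record")
  }
  locus_id <- sub("\\s.*$", "", names(ss)[1])
  ann <- utils::read.table(annotation_path, header = FALSE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  names(ann) <- c("chrom", "start", "end", "name", "score", "strand", "kind",
                  "pseudogene")[seq_len(ncol(ann))]
  if (any(ann$chrom != locus_id)) {
    stop("annotation rows reference sequence id(s) not in the FASTA: ",
         paste(unique(setdiff(ann$chrom, locus_id)), collapse = ", "))
  }
  regions <- tibble(name = ann$name, kind = ann$kind, start = ann$start,
                    end = ann$end, strand = ann$strand,
                    pseudogene = as.logical(ann$pseudogene))
  anc <- utils::read.table(anchors_path, header = FALSE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  names(anc) <- c("gene", "type", "pos")
  gene_reference(locus_id, as.character(ss[[1]]), regions, as_tibble(anc))
}

#' Write a gene reference to FASTA + annotation + anchors files
#'
#' @param ref A [gene_reference()].
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @return Invisibly, a named list of the three file paths.
#' @export
write_reference <- function(ref, dir, prefix = "locus") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fasta"))
  bed <- file.path(dir, paste0(prefix, ".regions.bed"))
  anc <- file.path(dir, paste0(prefix, ".anchors.tsv"))
  writeLines(c(paste0(">", ref$locus_id), ref$sequence), fa)
  con <- file(bed, "w")
  writeLines("#vdjalign-regions v1", con)
  utils::write.table(
    data.frame(ref$locus_id, ref$regions$start, ref$regions$end,
               ref$regions$name, 0L, ref$regions$strand, ref$regions$kind,
               as.integer(ref$regions$pseudogene)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  close(con)
  con <- file(anc, "w")
  writeLines("#vdjalign-anchors v1", con)
  utils::write.table(as.data.frame(ref$anchors), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(list(fasta = fa, annotation = bed, anchors = anc))
}

#' Regions overlapping a locus interval
#'
#' Returns every annotated region overlapping the interval plus the intergenic
#' gaps, with exact overlap lengths. For a non-overlapping annotation the
#' overlap lengths partition the interval.
#'
#' @param ref A [gene_reference()].
#' @param start,end 0-based half-open interval on the locus.
#' @return A tibble with columns `name`, `kind`, `label`, `start`, `end`,
#'   `overlap`, `pseudogene`, ordered along the locus. Intergenic pieces carry
#'   `kind = "INTERGENIC"` and `name = NA`.
#' @export
region_at <- function(ref, start, end) {
  if (start < 0 || end > ref$length || end <= start) {
    stop("interval [", start, ",", end, ") outside locus bounds or empty")
  }
  r <- ref$regions
  hit <- r[r$start < end & r$end > start, ]
  ov_len <- pmin(hit$end, end) - pmax(hit$start, start)
  out <- tibble(
    name = hit$name, kind = hit$kind, label = kind_to_label(hit$kind),
    start = hit$start, end = hit$end,
    overlap = ov_len,
    pseudogene = hit$pseudogene
  )
  # intergenic complement of the union of annotated overlaps
  if (nrow(hit) > 0) {
    iv <- cbind(pmax(hit$start, start), pmin(hit$end, end))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    gaps <- list()
    cur <- start
    for (i in seq_len(nrow(iv))) {
      if (iv[i, 1] > cur) gaps[[length(gaps) + 1]] <- c(cur, iv[i, 1])
      cur <- max(cur, iv[i, 2])
    }
    if (cur < end) gaps[[length(gaps) + 1]] <- c(cur, end)
  } else {
    gaps <- list(c(start, end))
  }
  if (length(gaps) > 0) {
    g <- do.call(rbind, gaps)
    out <- bind_rows(out, tibble(
      name = NA_character_, kind = "INTERGENIC", label = "INTERGENIC",
      start = g[, 1], end = g[, 2], overlap = g[, 2] - g[, 1],
      pseudogene = FALSE
    ))
  }
  arrange(out, .data$start, .data$end)
}

#' Dominant region of a locus interval
#'
#' The dominant label of an interval is the annotated kind with the largest
#' overlap (ties broken by the earlier region on the locus); an interval
#' overlapping no annotated region is intergenic. A segment counts as "from" a
#' region kind with a single overlapping base.
#'
#' @param ref A [gene_reference()].
#' @param start,end 0-based half-open locus interval.
#' @return A list with `kind`, `label`, `name`, `genes` (all regions of the
#'   dominant label overlapped, in locus order), `overlap`, `region_start`,
#'   `pseudogene` (any overlapped region of the dominant label is a
#'   pseudogene).
#' @export
dominant_region <- function(ref, start, end) {
  r <- ref$regions
  hit <- which(r$start < end & r$end > start)
  if (length(hit) == 0) {
    return(list(kind = "INTERGENIC", label = "INTERGENIC", name = NA_character_,
                genes = character(), overlap = end - start,
                region_start = NA_integer_, pseudogene = FALSE))
  }
  ov <- pmin(r$end[hit], end) - pmax(r$start[hit], start)
  best <- hit[order(-ov, r$start[hit])][1]
  label <- kind_to_label(r$kind[best])
  sibs <- hit[kind_to_label(r$kind[hit]) == label]
  list(kind = r$kind[best], label = label, name = r$name[best],
       genes = unique(r$name[sibs]),
       overlap = ov[match(best, hit)],
       region_start = r$start[best], pseudogene = any(r$pseudogene[sibs]))
}
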
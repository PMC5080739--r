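# Shared low-level helpers: sequences and CIGAR traces.
#
# CIGAR convention used throughout the package: run-length encoded over the
# ops '=' (match), 'X' (mismatch), 'I' (read base not in the reference) and
# 'D' (reference base not in the read). For minus-strand alignments the trace
# describes the reverse-complemented read walked 5'->3' along the reference;
# read_start/read_end are always stored on forward read coordinates.

 .vdj_cache <- new.env(parent = emptyenv())

#' Reverse-complement a nucleotide string
#'
#' @param x A character vector of A/C/G/T/N sequences.
#' @return The reverse complement, same length as `x`.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Expand a run-length CIGAR into per-column operations
#'
#' @param cigar A single CIGAR string such as `"35=1X20="`.
#' @return A character vector with one op (`=`, `X`, `I`, `D`) per column.
#' @export
cigar_ops <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar)) return(character())
  lens <- as.integer(strsplit(cigar, "[=XID]")[[1]])
  ops <- strsplit(gsub("[0-9]+", "", cigar), "")[[1]]
  rep(ops, lens)
}

#' Re-encode per-column operations as a CIGAR string
#' @param ops Character vector of per-column ops.
#' @return A CIGAR string; `""` for empty input.
#' @export
ops_to_cigar <- function(ops) {
  if (length(ops) == 0) return("")
  r <- rle(ops)
  paste0(r$lengths, r$values, collapse = "")
}

#' Per-column coordinates of an alignment trace
#'
#' Walks a CIGAR and returns, for every column, the 0-based offset of the read
#' base (in the strand-adjusted read) and of the reference base it touches.
#' Gap columns carry the offset of the next consuming position on their gapped
#' side.
#'
#' @param cigar CIGAR string.
#' @return A data frame with columns `op`, `read_off`, `ref_off`.
#' @export
cigar_table <- function(cigar) {
  ops <- cigar_ops(cigar)
  consume_read <- ops %in% c("=", "X", "I")
  consume_ref <- ops %in% c("=", "X", "D")
  data.frame(
    op = ops,
    read_off = cumsum(consume_read) - consume_read,
    ref_off = cumsum(consume_ref) - consume_ref,
    stringsAsFactors = FALSE
  )
}

#' Recompute score and identity from an alignment trace
#'
#' The stored score of every alignment must be reproducible from its trace;
#' this is the scoring authority used by trimming and by the test suite.
#' A gap run of length L costs `gap_open + L * gap_extend`.
#'
#' @param cigar CIGAR string.
#' @param params An [align_params()] list.
#' @return A list with `score`, `n_match`, `n_mismatch`, `n_gapcols`,
#'   `identity`.
#' @export
alignment_stats <- function(cigar, params = align_params()) {
  ops <- cigar_ops(cigar)
  if (length(ops) == 0) {
    return(list(score = NA_integer_, n_match = 0L, n_mismatch = 0L,
                n_gapcols = 0L, identity = NA_real_))
  }
  r <- rle(ops)
  sc <- 0L
  for (k in seq_along(r$values)) {
    sc <- sc + switch(r$values[k],
      "=" = r$lengths[k] * params$match,
      "X" = r$lengths[k] * params$mismatch,
      params$gap_open + r$lengths[k] * params$gap_extend
    )
  }
  nm <- sum(ops == "=")
  nx <- sum(ops == "X")
  ng <- sum(ops %in% c("I", "D"))
  list(score = as.integer(sc), n_match = nm, n_mismatch = nx, n_gapcols = ng,
       identity = nm / (nm + nx + ng))
}

# strand-adjusted read interval of an alignment row (0-based half-open)
adjusted_read_interval <- function(row, read_len) {
  if (row$strand == "+") c(row$read_start, row$read_end)
  else c(read_len - row$read_end, read_len - row$read_start)
}

read_fasta_or_fastq <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) {
    "fastq"
  } else {
    "fasta"
  }
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  tibble(read_id = sub("\\s.*$", "", names(ss)),
         sequence = toupper(as.character(ss)))
}
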
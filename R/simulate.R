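# Synthetic whole-locus reference and RACE-like read simulator with per-read
# ground truth, covering every regular and non-regular recombination class.
#
# The locus is a scaled-down receptor gene: V genes as exon1-intron-exon2
# blocks organised in families of high mutual identity (creating the
# repetitive V copies that make multi-hit alignment necessary), a D/J cluster,
# one C region, and intergenic spacers, including one long intergenic stretch
# upstream of the first D region from which intergenic read material is drawn
# (where aberrant intergenic transcripts concentrate in real RACE data).
# Regular reads model the spliced mRNA of a recombined receptor: joined V
# exons, a junction with trimmed ends and non-templated N bases, optionally a
# D remnant, a trimmed J, and constant-region sequence.

#' Simulator configuration
#'
#' Defaults reproduce the composition observed in RACE repertoire data from a
#' 454 run of the human TR-beta locus: about a third of reads regular, the
#' non-regular remainder dominated by J-without-V reads (themselves mostly
#' upstream extensions of the J region, then D-, C-, intergenic- and J-
#' partners) and intergenic-only reads.
#'
#' @param seed Integer RNG seed; all simulator output is byte-deterministic
#'   under it.
#' @param n_v,n_v_families,family_identity V-gene count, family count and
#'   within-family sequence identity.
#' @param n_d,n_j,n_c D/J/C region counts; one J is marked as a pseudogene
#'   (expressed pseudogenes must still be detected).
#' @param exon1_len,exon2_len,intron_range,d_len,j_len,c_len Region geometry
#'   (nt).
#' @param intergenic_range Range of intergenic spacer lengths (nt);
#'   `d_upstream_len` is the long stretch upstream of the first D.
#' @param j_spacing_range Spacing inside the J cluster (nt).
#' @param class_weights Named mixture weights over the regularity classes
#'   (normalised internally).
#' @param v_end_trim,d_trim,j_start_trim,n_add Junction model: maximal
#'   exonuclease trims and N-addition length (uniform over `0:max`).
#' @param d_prob Probability that a regular read retains a D remnant.
#' @param sub_rate,indel_rate Per-base substitution and indel error rates.
#' @param homopolymer_rate Optional 454-like homopolymer length error rate
#'   (off by default).
#' @param read_len_range Target read lengths (nt); reads are truncated in the
#'   constant region only, never inside V/J.
#' @param strand_flip_prob Probability a read is emitted reverse-complemented.
#' @param n_reads Default dataset size.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_v = 9L, n_v_families = 3L,
                       family_identity = 0.97, n_d = 2L, n_j = 6L, n_c = 1L,
                       exon1_len = 50L, exon2_len = 288L,
                       intron_range = c(250L, 400L), d_len = 14L, j_len = 50L,
                       c_len = 300L, intergenic_range = c(150L, 400L),
                       d_upstream_len = 1200L,
                       j_spacing_range = c(100L, 200L),
                       class_weights = NULL,
                       v_end_trim = 6L, d_trim = 4L, j_start_trim = 6L,
                       n_add = 10L, d_prob = 0.8, sub_rate = 0.01,
                       indel_rate = 0.002, homopolymer_rate = 0,
                       read_len_range = c(120L, 350L),
                       strand_flip_prob = 0.5, n_reads = 1000L) {
  if (is.null(class_weights)) {
    jgrp <- 0.657 * 0.58
    class_weights <- c(
      REGULAR = 0.343,
      J_NO_V = jgrp * 0.773, DJ = jgrp * 0.140, J_C = jgrp * 0.053,
      J_INTERGENIC = jgrp * 0.027, J_J = jgrp * 0.008,
      INTERGENIC_ONLY = 0.657 * 0.348,
      C_ONLY = 0.657 * 0.040, V_ONLY = 0.657 * 0.032
    )
  }
  stopifnot(n_v >= 1, n_j >= 1, n_c >= 1, n_v_families >= 1,
            family_identity > 0, family_identity <= 1,
            all(class_weights >= 0), sum(class_weights) > 0,
            sub_rate >= 0, sub_rate <= 1, indel_rate >= 0, indel_rate <= 1)
  bad <- setdiff(names(class_weights), setdiff(REGULARITY_CLASSES, "OTHER"))
  if (length(bad) > 0) stop("unknown class weight(s): ",
                            paste(bad, collapse = ", "))
  cw <- class_weights / sum(class_weights)
  structure(as.list(environment())[c(
    "seed", "n_v", "n_v_families", "family_identity", "n_d", "n_j", "n_c",
    "exon1_len", "exon2_len", "intron_range", "d_len", "j_len", "c_len",
    "intergenic_range", "d_upstream_len", "j_spacing_range", "v_end_trim",
    "d_trim", "j_start_trim", "n_add", "d_prob", "sub_rate", "indel_rate",
    "homopolymer_rate", "read_len_range", "strand_flip_prob", "n_reads"
  )] |> c(list(class_weights = cw)), class = "sim_config")
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute bases at rate `rate`, never touching `protect` (1-based offsets)
mutate_seq <- function(s, rate, protect = integer()) {
  b <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(b)) < rate)
  hit <- setdiff(hit, protect)
  for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
  paste(b, collapse = "")
}

#' Simulate a whole-locus gene reference
#'
#' @param cfg A [sim_config()].
#' @param dir Optional directory; when given, FASTA, region-annotation and
#'   anchors files are written there via [write_reference()].
#' @return A list with `ref` (a [gene_reference()]) and `files` (paths or
#'   `NULL`).
#' @export
simulate_reference <- function(cfg = sim_config(), dir = NULL) {
  set.seed(cfg$seed)
  rint <- function(rg) sample(seq.int(rg[1], rg[2]), 1)
  pieces <- character()
  regions <- list()
  anchors <- list()
  pos <- 0L
  emit <- function(s) {
    pieces[[length(pieces) + 1]] <<- s
    pos <<- pos + nchar(s)
  }
  add_region <- function(name, kind, start, end, pseudo = FALSE) {
    regions[[length(regions) + 1]] <<- tibble(
      name = name, kind = kind, start = start, end = end, strand = "+",
      pseudogene = pseudo)
  }
  # V families: ancestors mutated per member; the 2nd-CYS codon (TGT) sits 9
  # nt before the exon 2 end and is never mutated
  fam <- rep(seq_len(cfg$n_v_families), length.out = cfg$n_v)
  cys_off <- cfg$exon2_len - 9L
  anc_e1 <- lapply(seq_len(cfg$n_v_families), function(f) rand_seq(cfg$exon1_len))
  anc_e2 <- lapply(seq_len(cfg$n_v_families), function(f) {
    s <- rand_seq(cfg$exon2_len)
    paste0(substr(s, 1, cys_off), "TGT", substr(s, cys_off + 4L, cfg$exon2_len))
  })
  memb <- stats::ave(seq_len(cfg$n_v), fam, FUN = seq_along)
  emit(rand_seq(rint(cfg$intergenic_range)))
  for (i in seq_len(cfg$n_v)) {
    f <- fam[i]
    name <- sprintf("simV%d-%d", f, memb[i])
    # each member diverges from the family ancestor by half the target
    # divergence, so PAIRWISE identity between members ~ family_identity
    mrate <- (1 - cfg$family_identity) / 2
    e1 <- mutate_seq(anc_e1[[f]], mrate)
    e2 <- mutate_seq(anc_e2[[f]], mrate, protect = (cys_off + 1L):(cys_off + 3L))
    add_region(name, "V_EXON1", pos, pos + cfg$exon1_len)
    emit(e1)
    emit(rand_seq(rint(cfg$intron_range)))
    add_region(name, "V_EXON2", pos, pos + cfg$exon2_len)
    anchors[[length(anchors) + 1]] <- tibble(name = name, type = "V",
                                             pos = pos + cys_off)
    emit(e2)
    emit(rand_seq(rint(cfg$intergenic_range)))
  }
  # long intergenic stretch upstream of the first D
  emit(rand_seq(cfg$d_upstream_len))
  for (i in seq_len(cfg$n_d)) {
    add_region(sprintf("simD%d", i), "D", pos, pos + cfg$d_len)
    emit(rand_seq(cfg$d_len))
    emit(rand_seq(rint(cfg$intergenic_range)))
  }
  # J cluster; the phenylalanine codon (TTT) occupies J offsets 31..33, so the
  # anchor (last base) sits at offset 32 (0-based)
  for (i in seq_len(cfg$n_j)) {
    pseudo <- i == cfg$n_j && cfg$n_j > 1
    name <- if (pseudo) sprintf("simJ%dP", i) else sprintf("simJ%d", i)
    s <- rand_seq(cfg$j_len)
    s <- paste0(substr(s, 1, 30), "TTT", substr(s, 34, cfg$j_len))
    add_region(name, "J", pos, pos + cfg$j_len, pseudo)
    anchors[[length(anchors) + 1]] <- tibble(name = name, type = "J",
                                             pos = pos + 32L)
    emit(s)
    emit(rand_seq(rint(cfg$j_spacing_range)))
  }
  emit(rand_seq(rint(cfg$intergenic_range)))
  for (i in seq_len(cfg$n_c)) {
    add_region(if (cfg$n_c == 1) "simC" else sprintf("simC%d", i), "C_EXON",
               pos, pos + cfg$c_len)
    emit(rand_seq(cfg$c_len))
    emit(rand_seq(rint(cfg$intergenic_range)))
  }
  anch <- bind_rows(anchors)
  names(anch)[1] <- "gene"
  ref <- gene_reference("simlocus", paste(pieces, collapse = ""),
                        bind_rows(regions), anch)
  files <- if (!is.null(dir)) write_reference(ref, dir) else NULL
  list(ref = ref, files = files)
}

# region lookup helpers on an arbitrary gene_reference
pick_region <- function(ref, kind) {
  r <- ref$regions[ref$regions$kind == kind, ]
  r[sample(nrow(r), 1), ]
}
locus_sub <- function(ref, start, end) substr(ref$sequence, start + 1L, end)

apply_errors <- function(seq, cfg) {
  b <- strsplit(seq, "")[[1]]
  out <- character(0)
  n_sub <- 0L; n_ins <- 0L; n_del <- 0L
  for (i in seq_along(b)) {
    u <- stats::runif(1)
    if (u < cfg$sub_rate) {
      out <- c(out, sample(setdiff(c("A", "C", "G", "T"), b[i]), 1))
      n_sub <- n_sub + 1L
    } else if (u < cfg$sub_rate + cfg$indel_rate / 2) {
      n_del <- n_del + 1L # deletion: emit nothing
    } else if (u < cfg$sub_rate + cfg$indel_rate) {
      out <- c(out, sample(c("A", "C", "G", "T"), 1), b[i])
      n_ins <- n_ins + 1L
    } else {
      out <- c(out, b[i])
    }
  }
  if (cfg$homopolymer_rate > 0) {
    r <- rle(out)
    long <- which(r$lengths >= 3)
    for (k in long) {
      if (stats::runif(1) < cfg$homopolymer_rate) {
        r$lengths[k] <- max(1L, r$lengths[k] + sample(c(-1L, 1L), 1))
      }
    }
    out <- inverse.rle(r)
  }
  list(seq = paste(out, collapse = ""), n_sub = n_sub, n_ins = n_ins,
       n_del = n_del)
}

#' Simulate one read of a given recombination class
#'
#' Constructs the pre-error read for the class, applies the error model and
#' an optional strand flip, and records the generating truth. Uses the
#' current RNG state (seed control happens in [simulate_dataset()]).
#'
#' @param cfg A [sim_config()].
#' @param ref A [gene_reference()] from [simulate_reference()].
#' @param truth_class One of the regularity classes except `OTHER`.
#' @param read_id Identifier recorded in the truth.
#' @return A list with `sequence` (emitted read), `truth` (one-row tibble) and
#'   `segments` (truth tiling of the pre-error read).
#' @export
simulate_read <- function(cfg, ref, truth_class, read_id = "simread") {
  rint <- function(rg) sample(seq.int(rg[1], rg[2]), 1)
  need <- function(kind, n) {
    if (sum(ref$regions$kind == kind) < n) {
      stop("class ", truth_class, " requires >= ", n, " ", kind,
           " region(s) in the reference")
    }
  }
  segs <- list()
  pos <- 0L
  parts <- character()
  add <- function(s, label, gene = NA_character_, ref_start = NA_integer_,
                  ref_end = NA_integer_) {
    if (nchar(s) == 0) return(invisible())
    parts[[length(parts) + 1]] <<- s
    segs[[length(segs) + 1]] <<- tibble(
      read_id = read_id, label = label, gene = gene,
      read_start = pos, read_end = pos + nchar(s),
      ref_start = ref_start, ref_end = ref_end)
    pos <<- pos + nchar(s)
  }
  v_gene <- d_gene <- j_gene <- NA_character_
  cdr3 <- NULL
  c_reg <- pick_region(ref, "C_EXON")
  add_c_tail <- function() {
    keep <- min(rint(c(60L, 200L)), c_reg$end - c_reg$start)
    add(locus_sub(ref, c_reg$start, c_reg$start + keep), "C", c_reg$name,
        c_reg$start, c_reg$start + keep)
  }
  add_j <- function(trim_max = cfg$j_start_trim) {
    j <- pick_region(ref, "J")
    j_gene <<- j$name
    tr <- sample(0:trim_max, 1)
    add(locus_sub(ref, j$start + tr, j$end), "J", j$name, j$start + tr, j$end)
    j
  }
  if (truth_class == "REGULAR") {
    need("V_EXON2", 1); need("J", 1)
    vx <- ref$regions[ref$regions$kind == "V_EXON1", ]
    v1 <- vx[sample(nrow(vx), 1), ]
    v2 <- ref$regions[ref$regions$name == v1$name &
                        ref$regions$kind == "V_EXON2", ]
    v_gene <- v1$name
    off <- sample(0:min(30L, v1$end - v1$start - 20L), 1)
    add(locus_sub(ref, v1$start + off, v1$end), "V", v1$name,
        v1$start + off, v1$end)
    vtrim <- sample(0:cfg$v_end_trim, 1)
    e2_start_read <- pos
    add(locus_sub(ref, v2$start, v2$end - vtrim), "V", v1$name,
        v2$start, v2$end - vtrim)
    add(rand_seq(sample(0:cfg$n_add, 1)), "JUNCTION")
    if (cfg$n_d > 0 && stats::runif(1) < cfg$d_prob) {
      d <- pick_region(ref, "D")
      d_gene <- d$name
      d5 <- sample(0:cfg$d_trim, 1); d3 <- sample(0:cfg$d_trim, 1)
      if (d$end - d3 > d$start + d5) {
        add(locus_sub(ref, d$start + d5, d$end - d3), "D", d$name,
            d$start + d5, d$end - d3)
        add(rand_seq(sample(0:cfg$n_add, 1)), "JUNCTION")
      }
    }
    jtrim <- sample(0:cfg$j_start_trim, 1)
    j <- ref$regions[ref$regions$kind == "J", ]
    j <- j[sample(nrow(j), 1), ]
    j_gene <- j$name
    j_start_read <- pos
    add(locus_sub(ref, j$start + jtrim, j$end), "J", j$name,
        j$start + jtrim, j$end)
    add_c_tail()
    # truth CDR3: conserved Cys first base through Phe/Trp last base
    van <- ref$anchors[ref$anchors$gene == v_gene & ref$anchors$type == "V", ]
    jan <- ref$anchors[ref$anchors$gene == j_gene & ref$anchors$type == "J", ]
    cdr3_start <- e2_start_read + (van$pos - v2$start)
    cdr3_end <- j_start_read + (jan$pos - (j$start + jtrim)) + 1L
    cdr3 <- list(start = cdr3_start, end = cdr3_end)
  } else if (truth_class == "J_NO_V") {
    j <- pick_region(ref, "J")
    j_gene <- j$name
    u <- min(rint(c(60L, 180L)), j$start)
    add(locus_sub(ref, j$start - u, j$start), "UPSTREAM", j$name,
        j$start - u, j$start)
    add(locus_sub(ref, j$start, j$end), "J", j$name, j$start, j$end)
    add_c_tail()
  } else if (truth_class == "DJ") {
    need("D", 1)
    d <- pick_region(ref, "D")
    d_gene <- d$name
    u <- min(rint(c(30L, 80L)), d$start)
    d3 <- sample(0:cfg$d_trim, 1)
    add(locus_sub(ref, d$start - u, d$start), "UPSTREAM", d$name,
        d$start - u, d$start)
    add(locus_sub(ref, d$start, d$end - d3), "D", d$name, d$start, d$end - d3)
    add(rand_seq(sample(0:cfg$n_add, 1)), "JUNCTION")
    add_j()
    add_c_tail()
  } else if (truth_class == "J_C") {
    coff <- sample(0:max(0L, c_reg$end - c_reg$start - 120L), 1)
    clen <- min(rint(c(60L, 120L)), c_reg$end - c_reg$start - coff)
    add(locus_sub(ref, c_reg$start + coff, c_reg$start + coff + clen), "C",
        c_reg$name, c_reg$start + coff, c_reg$start + coff + clen)
    add(rand_seq(sample(0:cfg$n_add, 1)), "JUNCTION")
    add_j()
    add_c_tail()
  } else if (truth_class == "J_J") {
    need("J", 2)
    jr <- ref$regions[ref$regions$kind == "J", ]
    pick <- sample(nrow(jr), 2)
    ja <- jr[pick[1], ]; jb <- jr[pick[2], ]
    j_gene <- jb$name
    add(locus_sub(ref, ja$start, ja$end), "J", ja$name, ja$start, ja$end)
    add(locus_sub(ref, jb$start, jb$end), "J", jb$name, jb$start, jb$end)
    add_c_tail()
  } else if (truth_class == "J_INTERGENIC") {
    src <- intergenic_source(ref)
    len <- rint(c(100L, 250L))
    off <- sample(0:(src[2] - src[1] - len), 1)
    add(locus_sub(ref, src[1] + off, src[1] + off + len), "INTERGENIC", NA,
        src[1] + off, src[1] + off + len)
    add(rand_seq(sample(0:cfg$n_add, 1)), "JUNCTION")
    add_j()
    add_c_tail()
  } else if (truth_class == "INTERGENIC_ONLY") {
    src <- intergenic_source(ref)
    len <- rint(c(100L, 300L))
    off <- sample(0:(src[2] - src[1] - len), 1)
    add(locus_sub(ref, src[1] + off, src[1] + off + len), "INTERGENIC", NA,
        src[1] + off, src[1] + off + len)
  } else if (truth_class == "C_ONLY") {
    clen <- min(rint(c(100L, 250L)), c_reg$end - c_reg$start)
    coff <- sample(0:(c_reg$end - c_reg$start - clen), 1)
    add(locus_sub(ref, c_reg$start + coff, c_reg$start + coff + clen), "C",
        c_reg$name, c_reg$start + coff, c_reg$start + coff + clen)
  } else if (truth_class == "V_ONLY") {
    vx <- ref$regions[ref$regions$kind == "V_EXON1", ]
    v1 <- vx[sample(nrow(vx), 1), ]
    v2 <- ref$regions[ref$regions$name == v1$name &
                        ref$regions$kind == "V_EXON2", ]
    v_gene <- v1$name
    add(locus_sub(ref, v1$start, v1$end), "V", v1$name, v1$start, v1$end)
    vtrim <- sample(0:cfg$v_end_trim, 1)
    add(locus_sub(ref, v2$start, v2$end - vtrim), "V", v1$name,
        v2$start, v2$end - vtrim)
    add(rand_seq(sample(0:cfg$n_add, 1)), "JUNCTION")
  } else {
    stop("cannot simulate class ", truth_class)
  }
  # soft length cap: truncate the trailing constant-region segment only,
  # never inside V/J material
  target <- rint(cfg$read_len_range)
  if (length(segs) > 1) {
    last <- segs[[length(segs)]]
    if (last$label == "C" && pos > target) {
      newlen <- max(30L, target - last$read_start)
      if (newlen < last$read_end - last$read_start) {
        parts[[length(parts)]] <- substr(parts[[length(parts)]], 1, newlen)
        segs[[length(segs)]]$read_end <- last$read_start + newlen
        segs[[length(segs)]]$ref_end <- last$ref_start + newlen
        pos <- last$read_start + newlen
      }
    }
  }
  pre <- paste(unlist(parts), collapse = "")
  segments <- bind_rows(segs)
  err <- apply_errors(pre, cfg)
  flipped <- stats::runif(1) < cfg$strand_flip_prob
  emitted <- if (flipped) revcomp(err$seq) else err$seq
  truth <- tibble(
    read_id = read_id, class = truth_class,
    v_gene = v_gene, d_gene = d_gene, j_gene = j_gene,
    flipped = flipped, pre_error_length = nchar(pre),
    n_sub = err$n_sub, n_ins = err$n_ins, n_del = err$n_del,
    cdr3_start = if (is.null(cdr3)) NA_integer_ else cdr3$start,
    cdr3_end = if (is.null(cdr3)) NA_integer_ else cdr3$end,
    cdr3_seq = if (is.null(cdr3)) NA_character_ else
      substr(pre, cdr3$start + 1L, cdr3$end)
  )
  list(sequence = emitted, truth = truth, segments = segments)
}

# the long intergenic stretch upstream of the first D region
intergenic_source <- function(ref) {
  d <- ref$regions[ref$regions$kind == "D", ]
  if (nrow(d) > 0) {
    d1 <- min(d$start)
    before <- ref$regions[ref$regions$end <= d1, ]
    lo <- if (nrow(before) > 0) max(before$end) else 0L
    if (d1 - lo >= 400L) return(c(lo + 10L, d1 - 10L))
  }
  # fallback: largest gap between consecutive regions
  r <- arrange(ref$regions, .data$start)
  gaps <- cbind(c(0L, r$end), c(r$start, ref$length))
  gaps <- gaps[gaps[, 2] - gaps[, 1] >= 320L, , drop = FALSE]
  if (nrow(gaps) == 0) stop("reference has no intergenic stretch >= 320 nt")
  g <- gaps[which.max(gaps[, 2] - gaps[, 1]), ]
  c(g[1] + 10L, g[2] - 10L)
}

#' Simulate a read dataset with ground truth
#'
#' Draws `n` reads from the class mixture, deterministic under the
#' configuration seed (byte-identical FASTQ and truth files on repeat).
#'
#' @param cfg A [sim_config()].
#' @param ref A [gene_reference()]; simulated from `cfg` when omitted.
#' @param n Number of reads.
#' @param dir Optional output directory for `reads.fastq` and `truth.tsv`.
#' @return A list with `reads` (tibble: `read_id`, `sequence`), `truth`,
#'   `segments` (truth tilings), `ref` and `files`.
#' @export
simulate_dataset <- function(cfg = sim_config(), ref = NULL,
                             n = cfg$n_reads, dir = NULL) {
  if (is.null(ref)) ref <- simulate_reference(cfg)$ref
  set.seed(cfg$seed + 1L)
  classes <- sample(names(cfg$class_weights), n, replace = TRUE,
                    prob = cfg$class_weights)
  sims <- lapply(seq_len(n), function(i) {
    simulate_read(cfg, ref, classes[i], read_id = sprintf("simread%05d", i))
  })
  reads <- tibble(
    read_id = vapply(sims, function(s) s$truth$read_id, character(1)),
    sequence = vapply(sims, `[[`, character(1), "sequence"))
  truth <- bind_rows(lapply(sims, `[[`, "truth"))
  segments <- bind_rows(lapply(sims, `[[`, "segments"))
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fq <- file.path(dir, "reads.fastq")
    write_fastq(reads, fq)
    tr <- file.path(dir, "truth.tsv")
    utils::write.table(truth, tr, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- list(fastq = fq, truth = tr)
  }
  list(reads = reads, truth = truth, segments = segments, ref = ref,
       files = files)
}

#' Write reads as FASTQ with flat qualities
#'
#' @param reads Tibble with `read_id`, `sequence`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  lines <- character(4L * nrow(reads))
  lines[seq(1, length(lines), 4)] <- paste0("@", reads$read_id)
  lines[seq(2, length(lines), 4)] <- reads$sequence
  lines[seq(3, length(lines), 4)] <- "+"
  lines[seq(4, length(lines), 4)] <- strrep("I", nchar(reads$sequence))
  writeLines(lines, path)
  invisible(path)
}
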
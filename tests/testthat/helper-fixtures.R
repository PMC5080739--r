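# Fixtures built in code: tiny deterministic loci and hand-made alignment
# rows. Everything is generated at test time; nothing is read from disk.

rseq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a small handcrafted locus: 2 V genes sharing exon 1 (to exercise
# exon-consistency), 1 D, 2 J (one pseudogene), 1 C
tiny_reference <- function(seed = 42) {
  set.seed(seed)
  e1_shared <- rseq(50)
  e2a <- paste0(rseq(180), "TGT", rseq(6))          # 189 nt, Cys at 180..182
  e2b <- paste0(rseq(180), "TGT", rseq(6))
  intron <- function() rseq(260)
  gap <- function(n = 200) rseq(n)
  j1 <- paste0(rseq(30), "TTT", rseq(17))           # 50 nt, Phe at 30..32
  j2 <- paste0(rseq(30), "TTT", rseq(17))
  dseq <- rseq(14)
  cseq <- rseq(250)
  pieces <- list(gap(120), e1_shared, intron(), e2a, gap(), e1_shared,
                 intron(), e2b, gap(400), dseq, gap(250), j1, gap(150), j2,
                 gap(220), cseq, gap(100))
  starts <- cumsum(c(0L, vapply(pieces, nchar, integer(1))))
  at <- function(i) c(starts[i], starts[i + 1])
  regions <- tibble::tibble(
    name = c("tinyV1", "tinyV1", "tinyV2", "tinyV2", "tinyD1", "tinyJ1",
             "tinyJ2P", "tinyC"),
    kind = c("V_EXON1", "V_EXON2", "V_EXON1", "V_EXON2", "D", "J", "J",
             "C_EXON"),
    start = c(at(2)[1], at(4)[1], at(6)[1], at(8)[1], at(10)[1], at(12)[1],
              at(14)[1], at(16)[1]),
    end = c(at(2)[2], at(4)[2], at(6)[2], at(8)[2], at(10)[2], at(12)[2],
            at(14)[2], at(16)[2]),
    strand = "+", pseudogene = c(rep(FALSE, 6), TRUE, FALSE)
  )
  anchors <- tibble::tibble(
    gene = c("tinyV1", "tinyV2", "tinyJ1", "tinyJ2P"),
    type = c("V", "V", "J", "J"),
    pos = c(at(4)[1] + 180L, at(8)[1] + 180L, at(12)[1] + 32L,
            at(14)[1] + 32L)
  )
  gene_reference("tinylocus", paste(unlist(pieces), collapse = ""), regions,
                 anchors)
}

# an alignment row with consistent stats; cigar defaults to a perfect match
make_aln <- function(read_start, read_end, ref_start,
                     ref_end = ref_start + (read_end - read_start),
                     strand = "+", cigar = NULL, score = NULL,
                     read_id = "r1", params = align_params(),
                     provenance = "test") {
  if (is.null(cigar)) cigar <- paste0(read_end - read_start, "=")
  st <- alignment_stats(cigar, params)
  tibble::tibble(
    read_id = read_id, read_start = as.integer(read_start),
    read_end = as.integer(read_end), ref_start = as.integer(ref_start),
    ref_end = as.integer(ref_end), strand = strand,
    score = if (is.null(score)) st$score else as.integer(score),
    n_match = st$n_match, n_mismatch = st$n_mismatch,
    n_gapcols = st$n_gapcols, identity = st$identity, cigar = cigar,
    provenance = provenance
  )
}

# a cigar of given aligned length with a chosen number of mismatches spread
# through it (no gaps), for identity-sensitive tests
mismatchy_cigar <- function(len, n_mismatch) {
  if (n_mismatch == 0) return(paste0(len, "="))
  ops <- rep("=", len)
  ops[round(seq(2, len - 1, length.out = n_mismatch))] <- "X"
  ops_to_cigar(ops)
}

# minimal segment tibble for classify_read tests
make_segments <- function(labels, genes = NULL, strand = "+") {
  n <- length(labels)
  if (is.null(genes)) genes <- paste0("g", seq_len(n))
  tibble::tibble(
    read_id = "r1", label = labels, kind = labels, gene = genes,
    genes = as.list(genes),
    read_start = seq(0L, by = 60L, length.out = n),
    read_end = seq(50L, by = 60L, length.out = n),
    ref_start = seq(0L, by = 100L, length.out = n),
    ref_end = seq(50L, by = 100L, length.out = n),
    strand = strand, score = 150L, identity = 1,
    extends_upstream = FALSE, covers_pseudogene = FALSE,
    multi_hit_ambiguous = FALSE, putative_cdr3 = FALSE,
    cigar = "50="
  )
}

# shared simulated datasets for the acceptance suite, computed once
acc_env <- new.env()

acc_reference <- function() {
  if (is.null(acc_env$simref)) {
    acc_env$simref <- simulate_reference(sim_config(seed = 101))$ref
  }
  acc_env$simref
}

acc_zero <- function() {
  if (is.null(acc_env$zero)) {
    ref <- acc_reference()
    cfg <- sim_config(seed = 101, sub_rate = 0, indel_rate = 0)
    ds <- simulate_dataset(cfg, ref, n = 500)
    run <- run_pipeline(ds$reads, ref)
    acc_env$zero <- list(ds = ds, run = run)
  }
  acc_env$zero
}

acc_noisy <- function() {
  if (is.null(acc_env$noisy)) {
    ref <- acc_reference()
    cfg <- sim_config(seed = 202, sub_rate = 0.01, indel_rate = 0.002)
    ds <- simulate_dataset(cfg, ref, n = 1000)
    run <- run_pipeline(ds$reads, ref)
    acc_env$noisy <- list(ds = ds, run = run)
  }
  acc_env$noisy
}

# does each truth gene appear among the comma-joined calls?
call_hit <- function(calls, truth) {
  mapply(function(cl, tr) {
    tr %in% strsplit(cl, ",", fixed = TRUE)[[1]]
  }, calls, truth, USE.NAMES = FALSE)
}

# truth CDR3 interval mapped to forward coordinates of the emitted read
truth_cdr3_fwd <- function(truth) {
  start <- ifelse(truth$flipped, truth$pre_error_length - truth$cdr3_end,
                  truth$cdr3_start)
  end <- ifelse(truth$flipped, truth$pre_error_length - truth$cdr3_start,
                truth$cdr3_end)
  list(start = start, end = end)
}
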
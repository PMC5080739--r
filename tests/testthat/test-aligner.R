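test_that("find_anchors reports every copy of a repeated segment", {
  ref <- tiny_reference()
  params <- align_params()
  j1 <- ref$regions[ref$regions$name == "tinyJ1", ]
  # read = exact copy of a unique region: exactly one full-length anchor
  read <- substr(ref$sequence, j1$start + 1, j1$end)
  a <- find_anchors(read, ref, params)
  expect_equal(nrow(a[a$strand == "+", ]), 1)
  expect_equal(a$read_start[a$strand == "+"], 0)
  expect_equal(a$length[a$strand == "+"], nchar(read))
  expect_equal(a$ref_start[a$strand == "+"], j1$start)
  # read = copy of the shared V exon 1: one anchor per V gene copy
  v1 <- ref$regions[ref$regions$name == "tinyV1" &
                      ref$regions$kind == "V_EXON1", ]
  read2 <- substr(ref$sequence, v1$start + 1, v1$end)
  a2 <- find_anchors(read2, ref, params)
  fw <- a2[a2$strand == "+" & a2$length == nchar(read2), ]
  expect_equal(nrow(fw), 2)
  # an all-N read yields no anchors rather than an error
  expect_equal(nrow(find_anchors(strrep("N", 50), ref, params)), 0)
})

test_that("find_anchors equals the brute-force maximal-substring oracle", {
  set.seed(11)
  params <- align_params()
  for (trial in 1:6) {
    locus <- rseq(sample(2000:5000, 1))
    ref <- gene_reference("loc", locus,
                          tibble::tibble(name = "J1", kind = "J",
                                         start = 100L, end = 150L),
                          tibble::tibble(gene = character(),
                                         type = character(),
                                         pos = integer()))
    # half the reads carry real locus material (mutated), half are random
    read <- if (trial %% 2 == 0) {
      s <- sample(0:(nchar(locus) - 250), 1)
      x <- substr(locus, s + 1, s + 250)
      if (trial %% 4 == 0) x <- revcomp(x)
      mutate_pos <- sample(nchar(x), 5)
      xs <- strsplit(x, "")[[1]]
      xs[mutate_pos] <- sample(c("A", "C", "G", "T"), 5, replace = TRUE)
      paste(xs, collapse = "")
    } else {
      rseq(sample(100:300, 1))
    }
    got <- find_anchors(read, ref, params)
    want <- oracle_anchors(read, locus, params$min_anchor)
    expect_equal(anchor_key(got), anchor_key(want))
  }
})

test_that("align_read recovers exact and reverse-complement substrings", {
  ref <- tiny_reference()
  params <- align_params()
  c_reg <- ref$regions[ref$regions$kind == "C_EXON", ]
  piece <- substr(ref$sequence, c_reg$start + 1, c_reg$start + 120)
  fw <- align_read(piece, ref, params)
  expect_equal(fw$read_start[1], 0)
  expect_equal(fw$ref_start[1], c_reg$start)
  expect_equal(fw$identity[1], 1)
  expect_equal(fw$strand[1], "+")
  rc <- align_read(revcomp(piece), ref, params)
  expect_equal(rc$strand[1], "-")
  expect_equal(rc$ref_start[1], c_reg$start)
  expect_equal(rc$identity[1], 1)
  expect_equal(rc$read_start[1], 0)
})

test_that("strand symmetry: aligning the reverse complement mirrors reads", {
  ref <- tiny_reference()
  params <- align_params()
  set.seed(21)
  for (k in 1:5) {
    s <- sample(0:(ref$length - 200), 1)
    read <- substr(ref$sequence, s + 1, s + 150)
    a <- align_read(read, ref, params)
    b <- align_read(revcomp(read), ref, params)
    n <- nchar(read)
    mirrored <- data.frame(
      read_start = n - b$read_end, read_end = n - b$read_start,
      ref_start = b$ref_start, ref_end = b$ref_end,
      strand = ifelse(b$strand == "+", "-", "+"), score = b$score)
    key <- function(d) sort(sprintf("%d:%d:%d:%d:%s:%d", d$read_start,
                                    d$read_end, d$ref_start, d$ref_end,
                                    d$strand, d$score))
    expect_equal(key(a), key(mirrored))
  }
})

test_that("stored score and identity are recomputable from the trace", {
  ref <- tiny_reference()
  params <- align_params()
  set.seed(31)
  for (k in 1:10) {
    s <- sample(0:(ref$length - 300), 1)
    x <- substr(ref$sequence, s + 1, s + sample(120:250, 1))
    xs <- strsplit(x, "")[[1]]
    nmut <- sample(0:6, 1)
    if (nmut > 0) {
      pos <- sample(seq_along(xs), nmut)
      xs[pos] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
    }
    if (k %% 3 == 0) xs <- xs[-sample(seq_along(xs), 2)] # deletions
    read <- paste(xs, collapse = "")
    if (k %% 2 == 0) read <- revcomp(read)
    alns <- align_read(read, ref, params)
    for (i in seq_len(nrow(alns))) {
      st <- alignment_stats(alns$cigar[i], params)
      expect_identical(st$score, alns$score[i])
      expect_equal(st$identity, alns$identity[i])
      expect_identical(st$n_match, alns$n_match[i])
      expect_identical(st$n_gapcols, alns$n_gapcols[i])
    }
  }
})

test_that("raising breaklen never lowers the best single-alignment score", {
  ref <- tiny_reference()
  params <- align_params()
  set.seed(41)
  # constructed: two locus segments 300 nt apart joined in one read
  s1 <- substr(ref$sequence, 1201, 1300)
  s2 <- substr(ref$sequence, 1601, 1700)
  read <- paste0(s1, s2)
  a200 <- align_read(read, ref, params, breaklen = 200)
  a400 <- align_read(read, ref, params, breaklen = 400)
  expect_gte(max(a400$score), max(a200$score))
  expect_equal(nrow(a200[a200$score >= 250, ]), 2) # two separate pieces
  # random reads
  for (k in 1:5) {
    s <- sample(0:(ref$length - 450), 1)
    read <- paste0(substr(ref$sequence, s + 1, s + 120),
                   substr(ref$sequence, s + 250, s + 400))
    scores <- vapply(c(100L, 200L, 400L, 800L), function(bl) {
      max(align_read(read, ref, params, breaklen = bl)$score)
    }, numeric(1))
    expect_true(all(diff(scores) >= 0))
  }
})

test_that("a spliced V read yields separate exon alignments at the truth", {
  ref <- tiny_reference()
  v2e1 <- ref$regions[ref$regions$name == "tinyV2" &
                        ref$regions$kind == "V_EXON1", ]
  v2e2 <- ref$regions[ref$regions$name == "tinyV2" &
                        ref$regions$kind == "V_EXON2", ]
  read <- paste0(substr(ref$sequence, v2e1$start + 1, v2e1$end),
                 substr(ref$sequence, v2e2$start + 1, v2e2$end))
  alns <- align_read(read, ref)
  hits_e2 <- alns[alns$ref_start >= v2e2$start - 5 &
                    alns$ref_end <= v2e2$end + 5, ]
  expect_gte(nrow(hits_e2), 1)
  # exon 1 is shared between the two V genes: both copies hit
  hits_e1 <- alns[alns$read_end <= nchar(read) / 2 + 5 &
                    alns$score >= 140, ]
  expect_gte(nrow(hits_e1), 2)
})

test_that("the external-alignment adapter round-trips scored rows", {
  params <- align_params()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  rows <- dplyr::bind_rows(
    make_aln(0, 80, 1000, cigar = "60=1X19="),
    make_aln(90, 150, 2000, cigar = "30=2D30=")
  )
  utils::write.table(
    rows[, c("read_id", "read_start", "read_end", "ref_start", "ref_end",
             "strand", "n_match", "n_mismatch", "n_gapcols", "cigar")],
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_external_alignments(tsv, params)
  expect_equal(back$score, rows$score)
  expect_equal(back$identity, rows$identity)
  expect_equal(back$provenance, rep("external", 2))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("read_id\tread_start", bad)
  expect_error(read_external_alignments(bad), "lacks column")
})
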
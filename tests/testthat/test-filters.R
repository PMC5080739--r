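test_that("exon-consistency keeps only the partner-supported V gene", {
  ref <- tiny_reference()
  r <- ref$regions
  e1a <- r[r$name == "tinyV1" & r$kind == "V_EXON1", ]
  e1b <- r[r$name == "tinyV2" & r$kind == "V_EXON1", ]
  e2b <- r[r$name == "tinyV2" & r$kind == "V_EXON2", ]
  set <- dplyr::bind_rows(
    make_aln(0, 50, e1a$start, e1a$end, score = 150),
    make_aln(0, 50, e1b$start, e1b$end, score = 150),
    make_aln(50, 239, e2b$start, e2b$end, score = 500)
  )
  out <- filter_by_exon_consistency(set, ref)
  expect_equal(nrow(out), 2)
  expect_true(e1b$start %in% out$ref_start)
  expect_false(e1a$start %in% out$ref_start)
  # without any exon-2 member the ambiguity stands
  out2 <- filter_by_exon_consistency(set[1:2, ], ref)
  expect_equal(nrow(out2), 2)
  # symmetric: co-optimal exon-2 hits resolved by an exon-1 member
  e2a <- r[r$name == "tinyV1" & r$kind == "V_EXON2", ]
  set3 <- dplyr::bind_rows(
    make_aln(50, 239, e2a$start, e2a$end, score = 500),
    make_aln(50, 239, e2b$start, e2b$end, score = 500),
    make_aln(0, 50, e1b$start, e1b$end, score = 150)
  )
  out3 <- filter_by_exon_consistency(set3, ref)
  expect_equal(sort(out3$ref_start), sort(c(e2b$start, e1b$start)))
})

test_that("end-to-end: a spliced read of the shared exon resolves its V", {
  ref <- tiny_reference()
  r <- ref$regions
  e1 <- r[r$name == "tinyV2" & r$kind == "V_EXON1", ]
  e2 <- r[r$name == "tinyV2" & r$kind == "V_EXON2", ]
  read <- paste0(substr(ref$sequence, e1$start + 1, e1$end),
                 substr(ref$sequence, e2$start + 1, e2$end))
  set <- vdjalign:::apply_filter_stack(align_read(read, ref), ref,
                                       align_params(), filter_params())
  lab <- vdjalign:::member_labels(set, ref)
  e1_hits <- lab[lab$dom_kind == "V_EXON1", ]
  expect_equal(unique(e1_hits$dom_gene), "tinyV2")
})

test_that("putative-CDR3 alignments are flagged between V exon 2 and J", {
  ref <- tiny_reference()
  r <- ref$regions
  e2 <- r[r$name == "tinyV1" & r$kind == "V_EXON2", ]
  j <- r[r$name == "tinyJ1", ]
  d <- r[r$name == "tinyD1", ]
  gap_start <- j$start - 100L # intergenic upstream of J1
  set <- dplyr::bind_rows(
    make_aln(0, 189, e2$start, e2$end, score = 560),
    make_aln(195, 230, gap_start, gap_start + 35L, score = 100),
    make_aln(235, 280, j$start, j$end, score = 135)
  )
  flags <- identify_putative_cdr3(set, ref)
  expect_equal(flags, c(FALSE, TRUE, FALSE))
  # no J right neighbour: nothing flagged
  expect_equal(identify_putative_cdr3(set[1:2, ], ref), c(FALSE, FALSE))
  # minus-strand read: J, X, V_EXON2 in read order mirrors the rule
  set_m <- dplyr::bind_rows(
    make_aln(0, 45, j$start, j$end, strand = "-", score = 135),
    make_aln(50, 85, gap_start, gap_start + 35L, strand = "-", score = 100),
    make_aln(90, 279, e2$start, e2$end, strand = "-", score = 560)
  )
  expect_equal(identify_putative_cdr3(set_m, ref), c(FALSE, TRUE, FALSE))

  # the filter: D/J-dominant or long alignments survive, short others do not
  dseg <- make_aln(195, 209, d$start, d$end, score = 42)
  short_ig <- make_aln(195, 230, gap_start, gap_start + 35L, score = 100)
  long_ig <- make_aln(195, 255, gap_start, gap_start + 60L, score = 180)
  for (case in list(
    list(member = dseg, kept = TRUE),     # 14 nt but from a D region
    list(member = short_ig, kept = FALSE), # 35 nt intergenic
    list(member = long_ig, kept = TRUE)    # 60 nt boundary is inclusive
  )) {
    s <- dplyr::bind_rows(set[1, ], case$member, set[3, ])
    out <- filter_cdr3_alignments(s, c(FALSE, TRUE, FALSE), filter_params(),
                                  ref)
    expect_equal(nrow(out), if (case$kept) 3 else 2)
  }
})

test_that("short inferior intergenic alignments are filtered conjunctively", {
  ref <- tiny_reference()
  j <- ref$regions[ref$regions$name == "tinyJ1", ]
  ig_start <- j$end + 20L
  mk_ig <- function(len, n_mm) {
    make_aln(0, len, ig_start, ig_start + len,
             cigar = mismatchy_cigar(len, n_mm))
  }
  # 35 nt, identity ~0.91: both conditions met, removed
  bad <- mk_ig(35, 3)
  expect_lt(bad$identity, 0.95)
  expect_equal(nrow(filter_intergenic_alignments(bad, filter_params(), ref)),
               0)
  # 35 nt but clean: kept under the conjunctive default
  good <- mk_ig(35, 0)
  expect_equal(nrow(filter_intergenic_alignments(good, filter_params(), ref)),
               1)
  # ... and removed under the disjunctive switch
  expect_equal(nrow(filter_intergenic_alignments(
    good, filter_params(intergenic_rule = "disjunctive"), ref)), 0)
  # the rule only targets intergenic-dominant members
  jseg <- make_aln(0, 30, j$start, j$start + 30L,
                   cigar = mismatchy_cigar(30, 3))
  expect_equal(nrow(filter_intergenic_alignments(jseg, filter_params(), ref)),
               1)
})

test_that("the filter stack is idempotent and only removes alignments", {
  ref <- acc_reference()
  cfg <- sim_config(seed = 404)
  ds <- simulate_dataset(cfg, ref, n = 25)
  ap <- align_params()
  fp <- filter_params()
  for (i in seq_len(nrow(ds$reads))) {
    aln <- align_read(ds$reads$sequence[i], ref, ap,
                      read_id = ds$reads$read_id[i])
    set1 <- optimal_alignment_set(aln)
    s <- filter_by_exon_consistency(set1, ref)
    expect_lte(nrow(s), nrow(set1))
    fl <- identify_putative_cdr3(s, ref)
    s$putative_cdr3 <- fl
    s2 <- filter_cdr3_alignments(s, fl, fp, ref)
    expect_lte(nrow(s2), nrow(s))
    s3 <- filter_intergenic_alignments(s2, fp, ref)
    expect_lte(nrow(s3), nrow(s2))
    # applying the stack to its own output changes nothing
    again <- filter_intergenic_alignments(
      filter_cdr3_alignments(
        filter_by_exon_consistency(s3, ref),
        identify_putative_cdr3(filter_by_exon_consistency(s3, ref), ref),
        fp, ref),
      fp, ref)
    expect_equal(as.data.frame(again), as.data.frame(s3))
  }
})

# a locus with two V copies identical over 200 nt whose distinguishing
# sequence lies beyond a 250 nt gap: only a relaxed breaklen can bridge it
two_copy_reference <- function() {
  set.seed(90)
  # homopolymer barriers around the internal gap stop chance extension
  # matches, so the shared segment stays exactly co-optimal at the default
  # breaklen and only chain merging across the gap can break the tie
  S <- rseq(200)
  B <- paste0(strrep("A", 12), rseq(168))
  B2 <- paste0(strrep("A", 12), rseq(168))
  e1a <- rseq(40)
  e1b <- rseq(40)
  gapA <- paste0(strrep("C", 12), rseq(226), strrep("T", 12))
  gapB <- paste0(strrep("C", 12), rseq(226), strrep("T", 12))
  ex2a <- paste0(S, gapA, B)
  ex2b <- paste0(S, gapB, B2)
  pieces <- list(rseq(150), e1a, rseq(300), ex2a, rseq(400), e1b, rseq(300),
                 ex2b, rseq(350), paste0(rseq(30), "TTT", rseq(17)),
                 rseq(200), rseq(250), rseq(100))
  starts <- cumsum(c(0L, vapply(pieces, nchar, integer(1))))
  regions <- tibble::tibble(
    name = c("dupVa", "dupVa", "dupVb", "dupVb", "dupJ1", "dupC"),
    kind = c("V_EXON1", "V_EXON2", "V_EXON1", "V_EXON2", "J", "C_EXON"),
    start = starts[c(2, 4, 6, 8, 10, 12)],
    end = starts[c(3, 5, 7, 9, 11, 13)],
    strand = "+", pseudogene = FALSE)
  list(ref = gene_reference("duplocus", paste(unlist(pieces), collapse = ""),
                            regions,
                            tibble::tibble(gene = character(),
                                           type = character(),
                                           pos = integer())),
       S = S, B = B)
}

test_that("relaxed realignment resolves multi-V ambiguity when one stands out", {
  tc <- two_copy_reference()
  ref <- tc$ref
  ap <- align_params()
  fp <- filter_params()
  read <- paste0(tc$S, tc$B) # spliced over the 250 nt internal gap
  aln <- align_read(read, ref, ap)
  set <- vdjalign:::apply_filter_stack(aln, ref, ap, fp)
  amb <- vdjalign:::cooptimal_v_genes(set, ref)
  expect_equal(length(amb), 1)
  expect_setequal(amb[[1]]$genes, c("dupVa", "dupVb"))
  resolved <- resolve_multiple_v(set, read, ref, ap, fp)
  lab <- vdjalign:::member_labels(resolved, ref)
  expect_equal(unique(lab$dom_gene[lab$dom_label == "V"]), "dupVa")
  # a set with a single V annotation passes through untouched
  single <- set[set$read_start >= 200, ][1, ]
  expect_equal(as.data.frame(resolve_multiple_v(single, read, ref, ap, fp)),
               as.data.frame(single))
})

test_that("indistinguishable V copies keep their multi-V ambiguity", {
  tc <- two_copy_reference()
  ref <- tc$ref
  ap <- align_params()
  fp <- filter_params()
  read <- tc$S # shared region only: nothing can disambiguate
  aln <- align_read(read, ref, ap)
  set <- vdjalign:::apply_filter_stack(aln, ref, ap, fp)
  resolved <- resolve_multiple_v(set, read, ref, ap, fp)
  lab <- vdjalign:::member_labels(resolved, ref)
  expect_setequal(unique(lab$dom_gene[lab$dom_label == "V"]),
                  c("dupVa", "dupVb"))
})
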
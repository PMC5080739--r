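test_that("segments carry labels, gene lists and upstream/pseudogene flags", {
  ref <- tiny_reference()
  r <- ref$regions
  j1 <- r[r$name == "tinyJ1", ]
  j2 <- r[r$name == "tinyJ2P", ]
  # member fully inside a J region
  segs <- annotate_segments(make_aln(0, 45, j1$start, j1$start + 45L), ref)
  expect_equal(segs$label, "J")
  expect_equal(segs$gene, "tinyJ1")
  expect_false(segs$extends_upstream)
  # member reaching 120 nt upstream of the J: flagged
  up <- annotate_segments(make_aln(0, 165, j1$start - 120L, j1$end - 5L), ref)
  expect_equal(up$label, "J")
  expect_true(up$extends_upstream)
  # member spanning two J regions and the gap: one J segment, both names
  span <- annotate_segments(make_aln(0, j2$end - j1$start, j1$start, j2$end),
                            ref)
  expect_equal(span$label, "J")
  expect_setequal(span$genes[[1]], c("tinyJ1", "tinyJ2P"))
  expect_true(span$covers_pseudogene)
  # co-optimal siblings merge into one multi-hit segment
  e1a <- r[r$name == "tinyV1" & r$kind == "V_EXON1", ]
  e1b <- r[r$name == "tinyV2" & r$kind == "V_EXON1", ]
  sibs <- dplyr::bind_rows(
    make_aln(0, 50, e1a$start, e1a$end),
    make_aln(0, 50, e1b$start, e1b$end))
  ms <- annotate_segments(sibs, ref)
  expect_equal(nrow(ms), 1)
  expect_true(ms$multi_hit_ambiguous)
  expect_setequal(ms$genes[[1]], c("tinyV1", "tinyV2"))
  # intergenic member names its locus interval
  igs <- annotate_segments(make_aln(0, 60, j1$end + 20L, j1$end + 80L), ref)
  expect_equal(igs$label, "INTERGENIC")
  expect_match(igs$gene, "^intergenic:")
})

test_that("classify_read implements the read taxonomy with 5'-partner rules", {
  cases <- list(
    list(labels = c("V", "J", "C"), want = "REGULAR"),
    list(labels = c("V", "D", "J", "C"), want = "REGULAR"),
    list(labels = c("D", "J", "C"), want = "DJ"),
    list(labels = c("C", "J", "C"), want = "J_C"),
    list(labels = c("J", "J", "C"), want = "J_J"),
    list(labels = c("INTERGENIC", "J", "C"), want = "J_INTERGENIC"),
    list(labels = c("J", "C"), want = "J_NO_V"),
    list(labels = c("J"), want = "J_NO_V"),
    list(labels = c("INTERGENIC"), want = "INTERGENIC_ONLY"),
    list(labels = c("INTERGENIC", "INTERGENIC"), want = "INTERGENIC_ONLY"),
    list(labels = c("C"), want = "C_ONLY"),
    list(labels = c("V"), want = "V_ONLY"),
    list(labels = c("V", "C"), want = "V_ONLY"),
    list(labels = c("V", "INTERGENIC"), want = "OTHER")
  )
  for (cs in cases) {
    expect_equal(classify_read(make_segments(cs$labels)), cs$want)
  }
  # same J gene twice does not make a J_J read
  segs <- make_segments(c("J", "J", "C"), genes = c("J1", "J1", "C1"))
  expect_equal(classify_read(segs), "J_NO_V")
  # minus-strand reads are classified in transcript orientation
  segs_m <- make_segments(c("C", "J", "D"), strand = "-")
  expect_equal(classify_read(segs_m), "DJ")
  # empty input falls through to OTHER
  expect_equal(classify_read(make_segments(character())), "OTHER")
})

test_that("classify_read is total over random segment configurations", {
  set.seed(77)
  for (k in 1:200) {
    n <- sample(0:5, 1)
    labels <- sample(c("V", "D", "J", "C", "INTERGENIC"), n, replace = TRUE)
    cls <- classify_read(make_segments(labels))
    expect_length(cls, 1)
    expect_true(cls %in% vdjalign:::REGULARITY_CLASSES)
  }
})

test_that("CDR3 extraction recovers the simulated junction exactly", {
  ref <- acc_reference()
  cfg <- sim_config(seed = 17, sub_rate = 0, indel_rate = 0,
                    class_weights = c(REGULAR = 1))
  ds <- simulate_dataset(cfg, ref, n = 40)
  run <- run_pipeline(ds$reads, ref)
  expect_equal(nrow(run$cdr3), 40)
  m <- dplyr::inner_join(run$cdr3, ds$truth, by = "read_id")
  fwd <- truth_cdr3_fwd(m)
  expect_equal(m$read_start, fwd$start)
  expect_equal(m$read_end, fwd$end)
  expect_equal(m$nt, m$cdr3_seq)
  # junction starts at the conserved Cys codon and ends at the Phe codon
  expect_true(all(substr(m$nt, 1, 3) == "TGT"))
  expect_true(all(substr(m$nt, nchar(m$nt) - 2, nchar(m$nt)) == "TTT"))
  expect_equal(m$in_frame, nchar(m$nt) %% 3 == 0)
  # the IMGT-style interval excludes both anchor codons
  expect_equal(m$imgt_start - m$read_start, rep(3L, nrow(m)))
})

test_that("CDR3 is absent when the V alignment stops before the Cys anchor", {
  ref <- tiny_reference()
  r <- ref$regions
  e2 <- r[r$name == "tinyV1" & r$kind == "V_EXON2", ]
  j <- r[r$name == "tinyJ1", ]
  # V alignment ends 20 nt before the anchor at exon offset 180
  segs <- annotate_segments(dplyr::bind_rows(
    make_aln(0, 160, e2$start, e2$start + 160L),
    make_aln(170, 220, j$start, j$end)
  ), ref)
  read <- paste0(substr(ref$sequence, e2$start + 1, e2$start + 160),
                 rseq(10), substr(ref$sequence, j$start + 1, j$end), rseq(10))
  expect_null(extract_cdr3(segs, read, ref))
  # with the anchor covered the junction is reported, out of frame when its
  # length is not a multiple of three
  segs2 <- annotate_segments(dplyr::bind_rows(
    make_aln(0, 189, e2$start, e2$end),
    make_aln(199, 249, j$start, j$end)
  ), ref)
  read2 <- paste0(substr(ref$sequence, e2$start + 1, e2$end), rseq(10),
                  substr(ref$sequence, j$start + 1, j$end), rseq(5))
  cd <- extract_cdr3(segs2, read2, ref)
  expect_false(is.null(cd))
  expect_equal(cd$in_frame, nchar(cd$nt) %% 3 == 0)
  expect_equal(nchar(cd$aa), nchar(cd$nt) %/% 3)
})

test_that("compare_annotations categorises agreement patterns", {
  a <- tibble::tibble(read_id = c("r1", "r2", "r3", "r4", "r5", "r6"),
                      v_calls = c("V7", "V7,V9", "V7", "V7", "", "V1"),
                      j_calls = c("J2", "J2", "J2", "J2", "J1", "J1"))
  b <- tibble::tibble(read_id = c("r1", "r2", "r3", "r4", "r5", "r7"),
                      v_calls = c("V7", "V7", "V3", "V7,V8", "", ""),
                      j_calls = c("J2", "J2", "J2", "J2", "J1", ""))
  cmp <- compare_annotations(a, b)
  got <- setNames(cmp$reads$category, cmp$reads$read_id)
  expect_equal(unname(got["r1"]), "identical")
  expect_equal(unname(got["r2"]), "missing")  # b lacks one of the multi-V
  expect_equal(unname(got["r3"]), "distinct")
  expect_equal(unname(got["r4"]), "extra")
  expect_equal(unname(got["r5"]), "identical") # agreeing J-only calls
  expect_equal(cmp$tally$n[cmp$tally$category == "unannotated"], 2L)
  # non_vj: the second input saw no V or J at all
  b2 <- tibble::tibble(read_id = "r1", v_calls = "", j_calls = "")
  cmp2 <- compare_annotations(a[1, ], b2)
  expect_equal(cmp2$reads$category, "non_vj")
})
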
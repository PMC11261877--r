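test_that("rRNA features are classified with coverage and partial flags", {
  feats <- dplyr::bind_rows(
    rrna_feature("c1", 100, 1640, "+", "16S ribosomal RNA"),     # 1540 nt
    rrna_feature("c1", 2000, 3200, "+", "16S ribosomal RNA"),    # 1200 nt
    rrna_feature("c1", 4000, 4110, "+", "5S ribosomal RNA"),
    rrna_feature("c1", 5000, 7900, "+", "23S ribosomal RNA (partial)")
  )
  cls <- classify_rrna_features(feats)
  expect_equal(cls$gene, c("16S", "16S", "5S", "23S"))
  expect_equal(cls$coverage[1], 1540 / 1534)
  expect_false(cls$partial[1])
  expect_equal(cls$coverage[2], 1200 / 1534, tolerance = 1e-12)
  expect_true(cls$coverage[2] < 0.80)
  expect_true(cls$partial[2])
  expect_true(cls$partial[4])  # annotation-level partial tag
  # 5S never enters linking
  expect_equal(nrow(link_operons(cls)), 0L)
})

test_that("unclassifiable rRNA products warn and become gene = other", {
  feats <- rrna_feature("c1", 10, 400, "+", "mystery RNA")
  expect_warning(cls <- classify_rrna_features(feats), "unclassifiable")
  expect_equal(cls$gene, "other")
})

test_that("linking pairs each 16S with the nearest downstream 23S on one strand", {
  feats <- dplyr::bind_rows(
    rrna_feature("c1", 100, 1640, "+", "16S ribosomal RNA"),
    rrna_feature("c1", 2040, 4940, "+", "23S ribosomal RNA")
  )
  ops <- link_operons(classify_rrna_features(feats))
  expect_equal(nrow(ops), 1L)
  expect_equal(ops$its_len, 400L)
  expect_equal(ops$start, 100L)
  expect_equal(ops$end, 4940L)

  # strand mismatch: no operon
  feats2 <- dplyr::bind_rows(
    rrna_feature("c1", 100, 1640, "+", "16S ribosomal RNA"),
    rrna_feature("c1", 2040, 4940, "-", "23S ribosomal RNA")
  )
  expect_equal(nrow(link_operons(classify_rrna_features(feats2))), 0L)

  # minus strand: transcription runs right to left, 23S at lower coordinates
  feats3 <- dplyr::bind_rows(
    rrna_feature("c1", 100, 3000, "-", "23S ribosomal RNA"),
    rrna_feature("c1", 3400, 4940, "-", "16S ribosomal RNA")
  )
  ops3 <- link_operons(classify_rrna_features(feats3))
  expect_equal(nrow(ops3), 1L)
  expect_equal(ops3$its_len, 400L)
  expect_equal(ops3$strand, "-")
})

test_that("each 23S is consumed at most once and partial genes never link", {
  feats <- dplyr::bind_rows(
    rrna_feature("c1", 100, 1640, "+", "16S ribosomal RNA"),
    rrna_feature("c1", 5000, 6540, "+", "16S ribosomal RNA"),
    rrna_feature("c1", 7000, 9900, "+", "23S ribosomal RNA")
  )
  ops <- link_operons(classify_rrna_features(feats))
  # pairing is greedy in coordinate order: the first 16S claims the single
  # 23S (the resulting long spacer is for the ITS filter to judge), leaving
  # the second 16S unpaired
  expect_equal(nrow(ops), 1L)
  expect_equal(ops$s16_start, 100L)
  expect_equal(ops$its_len, 5360L)

  feats_partial <- dplyr::bind_rows(
    rrna_feature("c1", 100, 1300, "+", "16S ribosomal RNA"),  # < 80 % coverage
    rrna_feature("c1", 2000, 4900, "+", "23S ribosomal RNA")
  )
  expect_equal(nrow(link_operons(classify_rrna_features(feats_partial))), 0L)
})

test_that("overlapping 16S/23S annotations are rejected with a warning", {
  feats <- dplyr::bind_rows(
    rrna_feature("c1", 100, 1640, "+", "16S ribosomal RNA"),
    rrna_feature("c1", 1500, 4400, "+", "23S ribosomal RNA")
  )
  expect_warning(ops <- link_operons(classify_rrna_features(feats)),
                 "overlap")
  expect_equal(nrow(ops), 0L)
})

test_that("filters remove oversized-ITS and boundary-crossing operons", {
  mk_op <- function(its_len, start = 100L) {
    tibble::tibble(
      genome_id = "g", contig_id = "c1", strand = "+",
      s16_start = start, s16_end = start + 1540L,
      s23_start = start + 1540L + its_len,
      s23_end = start + 1540L + its_len + 2900L,
      its_start = start + 1540L, its_end = start + 1540L + its_len,
      its_len = its_len, start = start,
      end = start + 1540L + its_len + 2900L
    )
  }
  ops <- dplyr::bind_rows(
    mk_op(1600L),            # unlinked
    mk_op(1500L),            # exactly at the threshold: retained
    mk_op(400L),             # fine
    mk_op(400L, 8000L)       # runs past the contig end
  )
  assemblies <- tibble::tibble(genome_id = "g", contig_id = "c1",
                               length = 10000L)
  res <- filter_operons(ops, assemblies, max_its = 1500L)
  expect_equal(nrow(res$operons), 2L)
  expect_true(all(res$operons$its_len <= 1500L))
  expect_equal(sort(res$report$reason), c("boundary", "unlinked"))
  expect_equal(res$report$n, c(1L, 1L))
})

test_that("operon sequence extraction is strand-symmetric", {
  withr::with_seed(21, {
    s16 <- random_seq(1540); its <- random_seq(300); s23 <- random_seq(2900)
    pad <- random_seq(500)
  })
  contig_plus <- paste0(pad, s16, its, s23, pad)
  op <- tibble::tibble(
    genome_id = "g", contig_id = "c1", strand = "+",
    s16_start = 500L, s16_end = 2040L,
    s23_start = 2340L, s23_end = 5240L,
    its_start = 2040L, its_end = 2340L, its_len = 300L,
    start = 500L, end = 5240L
  )
  contigs <- tibble::tibble(genome_id = "g", contig_id = "c1",
                            sequence = contig_plus)
  got <- extract_operon_sequence(op, contigs)
  expect_equal(got$sequence, paste0(s16, its, s23))
  expect_equal(got$len16, 1540L)
  expect_equal(got$len23, 2900L)

  # same operon on the minus strand of the reverse-complemented contig
  L <- nchar(contig_plus)
  op_minus <- op
  op_minus$strand <- "-"
  op_minus$start <- L - op$end
  op_minus$end <- L - op$start
  op_minus$s16_start <- L - op$s16_end; op_minus$s16_end <- L - op$s16_start
  op_minus$s23_start <- L - op$s23_end; op_minus$s23_end <- L - op$s23_start
  contigs_rc <- tibble::tibble(genome_id = "g", contig_id = "c1",
                               sequence = reverse_complement(contig_plus))
  got_minus <- extract_operon_sequence(op_minus, contigs_rc)
  expect_equal(got_minus$sequence, got$sequence)

  # zero-length ITS degenerates to the 16S/23S concatenation
  op0 <- op
  op0$s23_start <- 2040L; op0$s23_end <- 4940L
  op0$its_start <- 2040L; op0$its_end <- 2040L; op0$its_len <- 0L
  op0$end <- 4940L
  contig0 <- paste0(pad, s16, s23, pad, its)
  got0 <- extract_operon_sequence(
    op0, tibble::tibble(genome_id = "g", contig_id = "c1", sequence = contig0))
  expect_equal(got0$sequence, paste0(s16, s23))
})

test_that("operon ids are unique and parse back to their fields", {
  ops <- tibble::tibble(
    genome_id = c("gA", "gA", "gB"),
    contig_id = c("c1", "c1", "c1"),
    start = c(100L, 6000L, 100L),
    end = c(5000L, 10900L, 5000L),
    strand = c("+", "-", "+")
  )
  withids <- assign_operon_ids(ops)
  expect_equal(length(unique(withids$operon_id)), 3L)
  back <- parse_operon_id(withids$operon_id)
  expect_equal(back$genome_id, ops$genome_id)
  expect_equal(back$start, ops$start)
  expect_equal(back$end, ops$end)
  expect_equal(back$strand, ops$strand)
  expect_error(assign_operon_ids(dplyr::bind_rows(ops[1, ], ops[1, ])),
               "collision")
})
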
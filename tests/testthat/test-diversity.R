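# assemble an operon tibble straight from region sequences
ops_from_regions <- function(genome_id, s16s, itss, s23s) {
  n <- length(s16s)
  tibble::tibble(
    genome_id = genome_id,
    operon_id = sprintf("%s|c1|%d-%d|+", genome_id, seq_len(n) * 10000,
                        seq_len(n) * 10000 + nchar(s16s) + nchar(itss) +
                          nchar(s23s)),
    sequence = paste0(s16s, itss, s23s),
    len16 = nchar(s16s), its_len = nchar(itss), len23 = nchar(s23s)
  )
}

test_that("identical operon copies give all-zero matrices in every region", {
  withr::with_seed(51, {
    s16 <- random_seq(1534); its <- random_seq(400); s23 <- random_seq(2924)
  })
  ops <- ops_from_regions("gA", rep(s16, 2), rep(its, 2), rep(s23, 2))
  div <- intragenomic_diversity(ops)
  expect_equal(nrow(div), 4L)  # one pair per region
  expect_true(all(div$distance == 0))
  expect_true(all(div$identity == 100))
})

test_that("mutations planted only in the ITS surface only in the ITS matrix", {
  withr::with_seed(52, {
    s16 <- random_seq(1534); its <- random_seq(400); s23 <- random_seq(2924)
    its2 <- mutate_region(its, 8)$sequence
    its3 <- mutate_region(its, 12)$sequence
  })
  ops <- ops_from_regions("gB", rep(s16, 3), c(its, its2, its3), rep(s23, 3))
  div <- intragenomic_diversity(ops)
  expect_true(all(div$distance[div$region %in% c("16S", "23S")] == 0))
  expect_true(all(div$distance[div$region == "ITS"] > 0))
  # planted substitution counts are recovered exactly (no indels planted)
  its_pair <- div[div$region == "ITS" & grepl("10000", div$id_a) &
                    grepl("20000", div$id_b), ]
  expect_equal(its_pair$distance * 400 / 100, 8)
  # and the whole-operon distance is consistent with the regional count
  rrn_pair <- div[div$region == "rrn" & grepl("10000", div$id_a) &
                    grepl("20000", div$id_b), ]
  expect_equal(rrn_pair$distance * nchar(ops$sequence[1]) / 100, 8)
})

test_that("four copies yield six pairs per region and genomes below two are skipped", {
  withr::with_seed(53, {
    s16 <- random_seq(200); its <- random_seq(100); s23 <- random_seq(300)
  })
  four <- ops_from_regions("gC", rep(s16, 4), rep(its, 4), rep(s23, 4))
  single <- ops_from_regions("gD", s16, its, s23)
  expect_message(div <- intragenomic_diversity(dplyr::bind_rows(four, single)),
                 "skipped")
  expect_equal(sum(div$region == "rrn"), 6L)
  expect_false("gD" %in% div$genome_id)
})

test_that("summary statistics pool pairs and count diverse genomes", {
  withr::with_seed(54, {
    s16 <- random_seq(500); its <- random_seq(200); s23 <- random_seq(700)
    make_genome <- function(g, diverse) {
      its_b <- if (diverse) mutate_region(its, 4)$sequence else its
      ops_from_regions(g, rep(s16, 2), c(its, its_b), rep(s23, 2))
    }
    ops <- dplyr::bind_rows(
      make_genome("g1", TRUE), make_genome("g2", TRUE),
      make_genome("g3", TRUE), make_genome("g4", FALSE)
    )
  })
  div <- intragenomic_diversity(ops)
  summ <- diversity_summary(div)
  rrn <- summ[summ$region == "rrn", ]
  expect_equal(rrn$fraction_genomes_diverse, 0.75)
  expect_equal(rrn$n_genomes, 4L)
  expect_equal(rrn$n_pairs, 4L)
  # independent one-pass recomputation of the pooled statistics
  ids <- div$identity[div$region == "rrn"]
  expect_equal(rrn$mean, sum(ids) / length(ids), tolerance = 1e-9)
  expect_equal(rrn$sd, sqrt(sum((ids - mean(ids))^2) / (length(ids) - 1)),
               tolerance = 1e-9)
  expect_equal(rrn$cv, 100 * rrn$sd / rrn$mean, tolerance = 1e-9)
})

test_that("region correlations behave at the self, driven and null extremes", {
  expect_equal(cor(c(1, 2, 3), c(1, 2, 3)), 1.0)
  withr::with_seed(55, {
    s16 <- random_seq(1000); its <- random_seq(500); s23 <- random_seq(1500)
    rows <- lapply(1:12, function(g) {
      # ITS carries nearly all of the operon's mutations
      k <- sample(0:12, 1)
      ops_from_regions(paste0("g", g), rep(s16, 2),
                       c(its, mutate_region(its, k)$sequence), rep(s23, 2))
    })
  })
  div <- intragenomic_diversity(dplyr::bind_rows(rows))
  cm <- region_correlation(div)
  expect_equal(cm["rrn", "rrn"], 1.0)
  expect_gt(cm["rrn", "ITS"], 0.95)

  # independent random identity vectors decorrelate within 3 / sqrt(n)
  withr::with_seed(56, {
    n <- 400
    x <- rnorm(n); y <- rnorm(n)
  })
  expect_lt(abs(cor(x, y)), 3 / sqrt(n))
})

test_that("distance matrices are symmetric, zero-diagonal and phylip-stable", {
  withr::with_seed(57, {
    s16 <- random_seq(400); its <- random_seq(150); s23 <- random_seq(600)
    ops <- ops_from_regions("gX", rep(s16, 3),
                            c(its, mutate_region(its, 3)$sequence,
                              mutate_region(its, 5)$sequence),
                            rep(s23, 3))
  })
  div <- intragenomic_diversity(ops)
  m <- distance_matrix(div, "gX", "ITS")
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))
  expect_true(all(m >= 0 & m <= 100))
  rownames(m) <- colnames(m) <- gsub("[|]", "_", rownames(m))
  f <- tempfile()
  write_phylip_distmat(m, f)
  expect_equal(read_phylip_distmat(f), m, tolerance = 1e-9)
  # identity + distance = 100 for every reported pair
  expect_equal(div$identity + div$distance, rep(100, nrow(div)))
})
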
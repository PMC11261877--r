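test_that("length sorting is descending with deterministic id tie-breaks", {
  seqs <- tibble::tibble(
    id = c("b", "a", "c"),
    sequence = c("ACGTA", "ACGTACGTA", "ACGTACG")
  )
  expect_equal(sort_by_length(seqs)$id, c("a", "c", "b"))
  ties <- tibble::tibble(id = c("z", "y"), sequence = c("ACGT", "AAAA"))
  expect_equal(sort_by_length(ties)$id, c("y", "z"))
  expect_equal(nrow(sort_by_length(seqs[0, ])), 0L)
})

test_that("greedy clustering groups near-identical sequences under a centroid", {
  withr::with_seed(31, {
    base <- random_seq(5000)
    mutants <- vapply(1:4, function(i) mutate_region(base, 2)$sequence,
                      character(1))
    outlier <- mutate_region(base, 500)$sequence  # ~90 % identity
  })
  seqs <- tibble::tibble(
    id = c("cent", paste0("mut", 1:4), "out"),
    sequence = c(base, mutants, outlier)
  )
  cl <- greedy_cluster(sort_by_length(seqs), threshold = 99.9)
  expect_equal(sort(cl$clusters$size), c(1L, 5L))
  big <- cl$clusters$cluster_id[cl$clusters$size == 5]
  expect_setequal(
    cl$members$member_id[cl$members$cluster_id == big],
    c("cent", paste0("mut", 1:4))
  )
  # every member meets the threshold against its representative
  expect_true(all(cl$members$identity_to_rep >= 99.9))
})

test_that("identical sequences cluster together; 99.0 % pairs stay apart at 99.9", {
  withr::with_seed(32, {
    a <- random_seq(5000)
    b <- mutate_region(a, 50)$sequence  # 99.0 % identity
  })
  same3 <- tibble::tibble(id = c("s1", "s2", "s3"),
                          sequence = rep(a, 3))
  expect_equal(greedy_cluster(same3, 99.9)$clusters$size, 3L)

  two <- sort_by_length(tibble::tibble(id = c("a", "b"), sequence = c(a, b)))
  expect_equal(pairwise_identity(a, b), 99.0)
  cl <- greedy_cluster(two, threshold = 99.9)
  expect_equal(nrow(cl$clusters), 2L)
})

test_that("clustering at threshold 100 groups exactly byte-identical sequences", {
  withr::with_seed(33, {
    u <- random_seq(800)
    v <- mutate_region(u, 1)$sequence
  })
  seqs <- sort_by_length(tibble::tibble(
    id = c("u1", "u2", "v1", "v2", "v3"),
    sequence = c(u, u, v, v, v)
  ))
  cl <- greedy_cluster(seqs, threshold = 100)
  expect_equal(sort(cl$clusters$size), c(2L, 3L))
  u_cluster <- cl$members$cluster_id[cl$members$member_id == "u1"]
  expect_setequal(cl$members$member_id[cl$members$cluster_id == u_cluster],
                  c("u1", "u2"))
})

test_that("the representative is always the longest member", {
  withr::with_seed(34, {
    long <- random_seq(2000)
    short <- substr(mutate_region(long, 1)$sequence, 1, 1990)
  })
  cl <- greedy_cluster(
    sort_by_length(tibble::tibble(id = c("short", "long"),
                                  sequence = c(short, long))),
    threshold = 99.5
  )
  expect_equal(nrow(cl$clusters), 1L)
  expect_equal(cl$clusters$representative_id, "long")
})

test_that("augmentation only admits sequences that expand diversity", {
  withr::with_seed(35, {
    r1 <- random_seq(4800)
    r2 <- mutate_region(r1, 480)$sequence    # far from r1
    novel <- mutate_region(r1, 240)$sequence # ~95 % to both
  })
  reps <- tibble::tibble(id = c("r1", "r2"), sequence = c(r1, r2))

  absorbed <- augment_clusters(reps,
                               tibble::tibble(id = "dup", sequence = r1),
                               threshold = 99.9)
  expect_equal(nrow(absorbed$clusters), 2L)
  expect_true("dup" %in% absorbed$members$member_id)

  expanded <- augment_clusters(reps,
                               tibble::tibble(id = "new", sequence = novel),
                               threshold = 99.9)
  expect_equal(nrow(expanded$clusters), 3L)

  unchanged <- augment_clusters(reps, reps[0, ], threshold = 99.9)
  expect_equal(nrow(unchanged$clusters), 2L)
})

test_that("two-phase dereplication keeps phase-1 memberships intact", {
  withr::with_seed(36, {
    base <- random_seq(4500)
    c2 <- mutate_region(base, 2)$sequence
    inc_same <- mutate_region(base, 1)$sequence   # absorbed in phase 2
    inc_new <- mutate_region(base, 400)$sequence  # novel diversity
  })
  complete <- tibble::tibble(id = c("g1", "g2"), sequence = c(base, c2))
  incomplete <- tibble::tibble(id = c("i1", "i2"),
                               sequence = c(inc_same, inc_new))
  dd <- derep_two_phase(complete, incomplete, threshold = 99.9)
  expect_equal(nrow(dd$clusters), 2L)
  expect_equal(dd$n_input, 4L)
  expect_setequal(dd$members$member_id, c("g1", "g2", "i1", "i2"))
  main <- dd$members$cluster_id[dd$members$member_id == "g1"]
  expect_setequal(dd$members$member_id[dd$members$cluster_id == main],
                  c("g1", "g2", "i1"))
  expect_true(all(dd$members$identity_to_rep >= 99.9))
})

test_that("consensus takes the column majority with fixed tie order", {
  expect_equal(consensus_sequence("ACGT"), "ACGT")
  expect_equal(consensus_sequence(c("ACGT", "ACGT", "ACTT")), "ACGT")
  # 50/50 base tie resolves by A < C < G < T
  expect_equal(consensus_sequence(c("ACGT", "ACTT")), "ACGT")
  withr::with_seed(37, {
    base <- random_seq(600)
    m1 <- mutate_region(base, 3)$sequence
  })
  # singletons and unanimous clusters reproduce the member
  expect_equal(consensus_sequence(c(base, base, base)), base)
  # a single dissenting member cannot outvote the majority
  expect_equal(consensus_sequence(c(base, base, m1)), base)
})

test_that("reduction percentages match worked examples", {
  expect_equal(reduction_percent(291365, 103991), 64.3)
  expect_equal(reduction_percent(317986, 103293), 67.5)
  expect_equal(reduction_percent(100, 100), 0.0)
  expect_error(reduction_percent(0, 10), "positive")
})

test_that("tidy and glance summarise a dereplication result", {
  withr::with_seed(38, {
    a <- random_seq(1000)
    b <- mutate_region(a, 300)$sequence
  })
  cl <- greedy_cluster(
    sort_by_length(tibble::tibble(id = c("a1", "a2", "b1"),
                                  sequence = c(a, a, b))),
    threshold = 99.9
  )
  td <- tidy(cl)
  expect_equal(nrow(td), 3L)
  expect_true(all(c("cluster_id", "member_id", "size") %in% names(td)))
  gl <- glance(cl)
  expect_equal(gl$n_input, 3L)
  expect_equal(gl$n_clusters, 2L)
  expect_equal(gl$reduction, reduction_percent(3, 2))
})
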
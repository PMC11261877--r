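test_that("lineage parsing and formatting are mutual inverses", {
  expect_equal(format_lineage(parse_lineage(ecoli_lineage)), ecoli_lineage)
  short <- parse_lineage("k__Bacteria")
  expect_equal(short$kingdom, "Bacteria")
  expect_true(all(short[, 2:7] == ""))
  expect_equal(format_lineage(short),
               "k__Bacteria;p__;c__;o__;f__;g__;s__")
  # bare (unprefixed) fields are accepted
  expect_equal(parse_lineage("Bacteria;Proteobacteria")$phylum,
               "Proteobacteria")
  expect_error(parse_lineage("k__;p__X"), "gap")
  expect_error(parse_lineage("a;b;c;d;e;f;g;h"), "seven")
})

test_that("the LCA is the deepest unanimous rank", {
  mix <- c(rep(ecoli_lineage, 97), rep(shigella_lineage, 3))
  expect_equal(parse_lineage(tax_lca(mix))$family, "Enterobacteriaceae")
  expect_equal(parse_lineage(tax_lca(mix))$genus, "")
  expect_equal(tax_lca(rep(ecoli_lineage, 5)), ecoli_lineage)
  disagreeing <- c("k__Bacteria", "k__Archaea")
  expect_equal(tax_lca(disagreeing), format_lineage(rep("", 7)))
  expect_error(tax_lca(character(0)), "empty")
})

test_that("majority taxonomy returns the lowest strict-majority prefix", {
  mix <- c(rep(ecoli_lineage, 97), rep(shigella_lineage, 3))
  expect_equal(tax_maj(mix), ecoli_lineage)
  # 50/50 split at species falls to the shared genus
  sp_a <- sub("s__Escherichia coli", "s__Escherichia alba", ecoli_lineage)
  tied <- c(rep(ecoli_lineage, 2), rep(sp_a, 2))
  out <- parse_lineage(tax_maj(tied))
  expect_equal(out$genus, "Escherichia")
  expect_equal(out$species, "")
  # unanimity: majority equals the LCA
  expect_equal(tax_maj(rep(shigella_lineage, 4)),
               tax_lca(rep(shigella_lineage, 4)))
})

test_that("majority votes pool over full prefixes, never bare names", {
  # the same genus name under two different families must not pool
  g1 <- format_lineage(c("Bacteria", "P1", "C1", "O1", "F1", "Homonym", "s1"))
  g2 <- format_lineage(c("Bacteria", "P1", "C1", "O1", "F2", "Homonym", "s2"))
  out <- parse_lineage(tax_maj(c(g1, g1, g2, g2)))
  expect_equal(out$genus, "")
  expect_equal(out$order, "O1")
})

test_that("majority is at least as deep as the LCA and truly a majority", {
  depth <- function(lin) sum(nzchar(unlist(parse_lineage(lin))))
  withr::with_seed(101, {
    for (rep_i in 1:40) {
      lins <- replicate(sample(2:9, 1), random_lineage(width = 2))
      lca <- tax_lca(lins)
      maj <- tax_maj(lins)
      expect_gte(depth(maj), depth(lca))
      # permutation invariance
      expect_equal(tax_maj(sample(lins)), maj)
      expect_equal(tax_lca(sample(lins)), lca)
      # recount: the winning prefix must be carried by > n/2 members
      d <- depth(maj)
      if (d > 0) {
        prefix_of <- function(l) {
          paste(unlist(parse_lineage(l))[seq_len(d)], collapse = ";")
        }
        votes <- sum(vapply(lins, prefix_of, "") == prefix_of(maj))
        expect_gt(votes * 2, length(lins))
      }
      # independent brute force: deepest rank whose most common full prefix
      # exceeds half, counted by hand
      brute <- ""
      for (r in 7:1) {
        pref <- vapply(lins, function(l) {
          v <- unlist(parse_lineage(l))[seq_len(r)]
          if (any(!nzchar(v))) NA_character_ else paste(v, collapse = ";")
        }, "")
        tab <- table(pref[!is.na(pref)])
        if (length(tab) && max(tab) * 2 > length(lins)) {
          win <- strsplit(names(tab)[which.max(tab)], ";", fixed = TRUE)[[1]]
          brute <- format_lineage(c(win, rep("", 7 - r)))
          break
        }
      }
      if (identical(brute, "")) brute <- format_lineage(rep("", 7))
      expect_equal(maj, brute)
    }
  })
})

test_that("cluster taxonomy systems work through a derep object", {
  members <- tibble::tibble(
    cluster_id = c(rep("NR000001", 3), "NR000002"),
    member_id = c("gE1|c1|0-10|+", "gE2|c1|0-10|+", "gS1|c1|0-10|+",
                  "gE1|c1|20-30|+"),
    identity_to_rep = 100,
    is_representative = c(TRUE, FALSE, FALSE, TRUE)
  )
  clusters <- tibble::tibble(
    cluster_id = c("NR000001", "NR000002"),
    representative_id = c("gE1|c1|0-10|+", "gE1|c1|20-30|+"),
    size = c(3L, 1L)
  )
  dd <- structure(list(clusters = clusters, members = members,
                       threshold = 99.9, n_input = 4L),
                  class = "rrn_derep")
  lineages <- tibble::tibble(
    genome_id = c("gE1", "gE2", "gS1"),
    lineage = c(ecoli_lineage, ecoli_lineage, shigella_lineage)
  )
  tax <- cluster_taxonomy(dd, lineages)
  # representative lineage ignores the other members
  expect_equal(tax$taxRep[1], ecoli_lineage)
  expect_equal(parse_lineage(tax$taxLCA[1])$family, "Enterobacteriaceae")
  expect_equal(tax$taxMaj[1], ecoli_lineage)
  # two clusters sharing a source genome share a taxRep
  expect_equal(tax$taxRep[2], tax$taxRep[1])
  expect_error(cluster_taxonomy(dd, lineages[-1, ]), "missing")
})

test_that("species agreement fraction counts fully consistent clusters", {
  mk <- function(cluster_sizes, mixed) {
    ids <- unlist(lapply(seq_along(cluster_sizes), function(i) {
      genomes <- if (i %in% mixed) {
        c("gE1", rep("gS1", cluster_sizes[i] - 1))
      } else {
        rep("gE1", cluster_sizes[i])
      }
      sprintf("%s|c1|%d-%d|+", genomes, seq_along(genomes) * 10 + i * 1000,
              seq_along(genomes) * 10 + i * 1000 + 5)
    }))
    cl <- rep(sprintf("NR%06d", seq_along(cluster_sizes)), cluster_sizes)
    structure(list(
      clusters = tibble::tibble(
        cluster_id = unique(cl),
        representative_id = ids[!duplicated(cl)],
        size = cluster_sizes
      ),
      members = tibble::tibble(cluster_id = cl, member_id = ids,
                               identity_to_rep = 100,
                               is_representative = !duplicated(cl)),
      threshold = 99.9, n_input = length(ids)
    ), class = "rrn_derep")
  }
  lineages <- tibble::tibble(genome_id = c("gE1", "gS1"),
                             lineage = c(ecoli_lineage, shigella_lineage))
  expect_equal(species_agreement_fraction(mk(c(1, 1, 1, 1), integer(0)),
                                          lineages), 100)
  expect_equal(species_agreement_fraction(mk(c(3, 1, 1, 1), 1), lineages), 75)
})

test_that("phylum composition conserves counts and buckets unclassified", {
  lins <- c(rep("k__Bacteria;p__Proteobacteria", 3), "k__Bacteria;p__Firmicutes")
  comp <- phylum_composition(lins)
  expect_equal(comp$percent[comp$phylum == "Proteobacteria"], 75)
  expect_equal(comp$percent[comp$phylum == "Firmicutes"], 25)
  expect_equal(sum(comp$count), 4L)
  expect_equal(sum(comp$percent), 100, tolerance = 1e-9)
  expect_equal(phylum_composition("k__Bacteria")$phylum, "unclassified")
  expect_equal(nrow(phylum_composition(character(0))), 0L)
})
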
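random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# replace a substring of s at 1-based positions [at, at + nchar(piece) - 1]
splice_in <- function(s, at, piece) {
  paste0(substr(s, 1, at - 1L), piece,
         substr(s, at + nchar(piece), nchar(s)))
}

# pick one concrete expansion of an IUPAC string (first base in A<C<G<T
# order per position) -- used to plant intact primer sites
concretize_iupac <- function(x) {
  bases <- c("A", "C", "G", "T")
  v <- vapply(iupac_encode(x, "primer"), function(b) {
    bases[which(bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L)[1]]
  }, character(1))
  paste(v, collapse = "")
}

# 0-based intervals of the planted primer-site motifs within each template
primer_site_intervals <- function() {
  p <- rrn_primers()
  list(
    s16 = list(c(0L, 20L), c(500L, 515L)),          # 27F, 519F
    s23 = list(c(2224L, 2241L), c(2410L, 2428L))    # 2241R, 2428R
  )
}

#' Synthetic 16S and 23S template genes
#'
#' Deterministic synthetic gene templates of canonical length (16S:
#' 1534 nt, 23S: 2924 nt) carrying intact binding-site motifs for the
#' bundled primer pairs ([rrn_primers()]): one concrete expansion of 27F
#' and 519F inside the 16S, and the reverse complements of 2241R and 2428R
#' at the matching positions of the 23S. They are synthetic sequences, not
#' real gene sequences; outside the planted motifs the bases are uniform
#' random draws from a fixed internal seed, so the templates are identical
#' across calls and platforms.
#'
#' @return A list with elements `s16` and `s23`.
#' @export
rrn_templates <- function() {
  withr::with_seed(19880301L, {
    s16 <- random_dna(1534L)
    s23 <- random_dna(2924L)
    pr <- rrn_primers()
    s16 <- splice_in(s16, 1L, concretize_iupac(pr$fwd[1]))         # 27F
    s16 <- splice_in(s16, 501L, concretize_iupac(pr$fwd[3]))       # 519F
    s23 <- splice_in(s23, 2225L, reverse_complement(concretize_iupac(pr$rev[1])))
    s23 <- splice_in(s23, 2411L, reverse_complement(concretize_iupac(pr$rev[3])))
    list(s16 = s16, s23 = s23)
  })
}

#' Plant a fixed number of substitutions in a sequence
#'
#' Substitutes exactly `n_subs` distinct positions, never silently
#' restoring the original base, so planted Hamming distances are exact and
#' downstream distance computations can be checked against the truth.
#' Draws from the current RNG state.
#'
#' @param seq Input sequence (A/C/G/T).
#' @param n_subs Number of substitutions (at most the number of eligible
#'   positions).
#' @param exclude Optional integer vector of 1-based positions to protect
#'   (e.g. planted primer sites).
#' @return List with `sequence` (mutated) and `positions` (1-based, sorted).
#' @export
mutate_region <- function(seq, n_subs, exclude = integer(0)) {
  n <- nchar(seq)
  eligible <- setdiff(seq_len(n), exclude)
  if (n_subs > length(eligible)) {
    stop("n_subs exceeds the number of eligible positions", call. = FALSE)
  }
  if (n_subs == 0) return(list(sequence = seq, positions = integer(0)))
  pos <- sort(sample(eligible, n_subs))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  list(sequence = paste(chars, collapse = ""), positions = pos)
}

#' Configuration for the synthetic-genome simulator
#'
#' Defaults emulate the broad features reported for large genome
#' collections: around five rRNA operon copies per genome, ITS lengths
#' centred near 440 nt with large spread, most intragenomic variation
#' carried by the ITS, and a mix of plus- and minus-strand operons.
#' Primer-site motifs are protected from mutation by default, mirroring
#' the biological conservation of primer binding regions.
#'
#' @param n_genomes Number of genomes to simulate.
#' @param n_lineages Number of distinct lineages (species); genomes cycle
#'   through them. Lineage founder operons diverge from the shared
#'   templates at `lineage_divergence`.
#' @param copy_number Mean rRNA operon copies per genome.
#' @param copy_number_dist `"fixed"` (every genome gets
#'   `round(copy_number)`) or `"poisson"` (`1 + Poisson(copy_number - 1)`).
#' @param its_mean,its_sd,its_min ITS length distribution (normal draw,
#'   rounded, clipped to `[its_min, 1400]` so that only deliberately
#'   planted oversized spacers exceed the 1.5 kb filter).
#' @param mut_16s,mut_its,mut_23s Mean per-copy substitution counts per
#'   region (Poisson draws).
#' @param lineage_divergence Per-base substitution rate separating lineage
#'   founders from the shared templates (default 0.05, far below any
#'   dereplication threshold's radius).
#' @param frac_minus Fraction of operons planted on the minus strand.
#' @param frac_partial,frac_oversized_its,frac_origin_cross Fractions of
#'   operons planted with a disqualifying anomaly: a truncated (partial)
#'   16S gene, an ITS longer than 1.5 kb, or an annotation crossing the
#'   contig end.
#' @param frac_incomplete Fraction of genomes labelled as incomplete
#'   assemblies (entering database construction in phase 2).
#' @param include_5s Also plant a 5S gene downstream of plus-strand
#'   operons (exercises feature classification).
#' @param protect_primer_sites Exclude planted primer-site motifs from
#'   mutation (default `TRUE`).
#' @param pad,spacer Flanking and inter-operon random DNA lengths (nt).
#' @param seed Integer seed; the seed fully determines the fixture.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_genomes = 5L, n_lineages = min(n_genomes, 3L),
                         copy_number = 5, copy_number_dist = c("fixed", "poisson"),
                         its_mean = 440, its_sd = 150, its_min = 80L,
                         mut_16s = 1, mut_its = 2, mut_23s = 1,
                         lineage_divergence = 0.05,
                         frac_minus = 0.5, frac_partial = 0,
                         frac_oversized_its = 0, frac_origin_cross = 0,
                         frac_incomplete = 0, include_5s = TRUE,
                         protect_primer_sites = TRUE,
                         pad = 1000L, spacer = 500L, seed = 1L) {
  copy_number_dist <- match.arg(copy_number_dist)
  fr <- c(frac_minus, frac_partial, frac_oversized_its, frac_origin_cross,
          frac_incomplete)
  if (any(fr < 0 | fr > 1)) {
    stop("fractions must be in [0, 1]", call. = FALSE)
  }
  if (frac_partial + frac_oversized_its + frac_origin_cross > 1) {
    stop("anomaly fractions must sum to at most 1", call. = FALSE)
  }
  structure(
    list(n_genomes = as.integer(n_genomes),
         n_lineages = as.integer(n_lineages),
         copy_number = copy_number, copy_number_dist = copy_number_dist,
         its_mean = its_mean, its_sd = its_sd, its_min = as.integer(its_min),
         mut_16s = mut_16s, mut_its = mut_its, mut_23s = mut_23s,
         lineage_divergence = lineage_divergence,
         frac_minus = frac_minus, frac_partial = frac_partial,
         frac_oversized_its = frac_oversized_its,
         frac_origin_cross = frac_origin_cross,
         frac_incomplete = frac_incomplete,
         include_5s = isTRUE(include_5s),
         protect_primer_sites = isTRUE(protect_primer_sites),
         pad = as.integer(pad), spacer = as.integer(spacer),
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

synth_lineage_string <- function(i) {
  sprintf("k__Bacteria;p__Simphylum_%02d;c__Simclass_%02d;o__Simorder_%02d;f__Simfamily_%02d;g__Simgenus_%02d;s__Simgenus_%02d species_%02d",
          (i - 1L) %/% 2L + 1L, i, i, i, i, i, i)
}

#' Generate a synthetic genome fixture with planted operons
#'
#' Writes, for each simulated genome, a FASTA contig and a GFF3 annotation
#' with planted 16S-ITS-23S operons built from the fixed gene templates
#' ([rrn_templates()]), mutated per region at the configured rates, plus a
#' manifest TSV, a truth table TSV recording every planted operon
#' (coordinates, strand, per-region substitution counts, anomaly flag and
#' whether it should survive extraction and filtering) and a JSON echo of
#' the configuration. Output is byte-identical for equal seeds.
#'
#' @param config A [synth_config()] object.
#' @param dir Output directory (created if needed).
#' @return A list with `dir`, `manifest` (tibble: `genome_id`, `fasta`,
#'   `gff`, `assembly_level`, `lineage`), `truth` (tibble) and `config`,
#'   invisibly classed as `rrn_fixture`.
#' @export
generate_fixture <- function(config = synth_config(), dir = tempfile("fixture")) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tpl <- rrn_templates()
  sites <- primer_site_intervals()
  protect16 <- if (config$protect_primer_sites) {
    unlist(lapply(sites$s16, function(iv) (iv[1] + 1L):iv[2]))
  } else integer(0)
  protect23 <- if (config$protect_primer_sites) {
    unlist(lapply(sites$s23, function(iv) (iv[1] + 1L):iv[2]))
  } else integer(0)

  withr::with_seed(config$seed, {
    founders <- lapply(seq_len(config$n_lineages), function(l) {
      # the ITS is lineage-level too: genomes of one lineage share it
      # (modulo per-copy substitutions), so between-lineage divergence and
      # within-lineage cohesion are both controlled
      its_len <- max(config$its_min, min(1400L, as.integer(round(
        rnorm(1, config$its_mean, config$its_sd)))))
      list(
        s16 = mutate_region(tpl$s16,
                            round(config$lineage_divergence * nchar(tpl$s16)),
                            exclude = protect16)$sequence,
        s23 = mutate_region(tpl$s23,
                            round(config$lineage_divergence * nchar(tpl$s23)),
                            exclude = protect23)$sequence,
        its = random_dna(its_len)
      )
    })
    manifest <- list()
    truth <- list()
    for (gi in seq_len(config$n_genomes)) {
      genome_id <- sprintf("G%04d", gi)
      contig_id <- paste0(genome_id, "_c1")
      li <- (gi - 1L) %% config$n_lineages + 1L
      lineage <- synth_lineage_string(li)
      assembly_level <- if (runif(1) < config$frac_incomplete) {
        "incomplete"
      } else {
        "complete"
      }
      k <- switch(config$copy_number_dist,
        fixed = max(1L, as.integer(round(config$copy_number))),
        poisson = 1L + rpois(1, max(0, config$copy_number - 1))
      )
      base_its <- founders[[li]]$its
      base_its_len <- nchar(base_its)
      u <- runif(k)
      anomaly <- ifelse(u < config$frac_partial, "partial",
                 ifelse(u < config$frac_partial + config$frac_oversized_its,
                        "oversized_its",
                 ifelse(u < config$frac_partial + config$frac_oversized_its +
                          config$frac_origin_cross, "origin_cross", "none")))
      # an origin-crossing operon must sit at the contig end: keep one at
      # most, demote extras, and emit it last
      oc <- which(anomaly == "origin_cross")
      if (length(oc) > 1) anomaly[oc[-1]] <- "none"
      ord <- order(anomaly == "origin_cross")
      anomaly <- anomaly[ord]

      pieces <- character(0)
      cursor <- 0L
      feats <- list()
      tr <- list()
      emit <- function(piece) {
        pieces[[length(pieces) + 1L]] <<- piece
        cursor <<- cursor + nchar(piece)
      }
      feat <- function(start, end, strand, product) {
        feats[[length(feats) + 1L]] <<- tibble::tibble(
          contig_id = contig_id, source = "synth", type = "rRNA",
          start = start, end = end, score = NA_real_, strand = strand,
          phase = NA_integer_,
          attributes = paste0("product=", product)
        )
      }
      emit(random_dna(config$pad))
      for (ci in seq_len(k)) {
        an <- anomaly[ci]
        strand <- if (an == "origin_cross") "+" else {
          if (runif(1) < config$frac_minus) "-" else "+"
        }
        n16 <- rpois(1, config$mut_16s)
        nits <- rpois(1, config$mut_its)
        n23 <- rpois(1, config$mut_23s)
        s16 <- mutate_region(founders[[li]]$s16, n16, exclude = protect16)$sequence
        s23 <- mutate_region(founders[[li]]$s23, n23, exclude = protect23)$sequence
        if (an == "oversized_its") {
          its_len <- sample(1600:2400, 1)
          its <- random_dna(its_len)
          nits <- 0L
        } else {
          its_len <- base_its_len
          nits <- min(nits, its_len)
          its <- mutate_region(base_its, nits)$sequence
        }
        if (an == "partial") {
          s16 <- substr(s16, 1L, as.integer(round(0.74 * nchar(s16))))
        }
        l16 <- nchar(s16); l23 <- nchar(s23)
        product16 <- if (an == "partial") {
          "16S ribosomal RNA (partial)"
        } else {
          "16S ribosomal RNA"
        }
        if (ci > 1L) emit(random_dna(config$spacer))
        op_start <- cursor
        if (an == "origin_cross") {
          # annotate the full 23S but only emit its first kilobase; the
          # annotated operon interval then crosses the contig end
          emit(s16)
          emit(its)
          emit(substr(s23, 1L, min(1000L, l23)))
          feat(op_start, op_start + l16, "+", product16)
          feat(op_start + l16 + its_len,
               op_start + l16 + its_len + l23, "+", "23S ribosomal RNA")
          op_end <- op_start + l16 + its_len + l23
        } else if (strand == "+") {
          emit(s16); emit(its); emit(s23)
          feat(op_start, op_start + l16, "+", product16)
          feat(op_start + l16 + its_len,
               op_start + l16 + its_len + l23, "+", "23S ribosomal RNA")
          op_end <- cursor
          if (config$include_5s) {
            emit(random_dna(80L))
            s5_start <- cursor
            emit(random_dna(110L))
            feat(s5_start, cursor, "+", "5S ribosomal RNA")
          }
        } else {
          emit(reverse_complement(paste0(s16, its, s23)))
          feat(op_start, op_start + l23, "-", "23S ribosomal RNA")
          feat(op_start + l23 + its_len, cursor, "-", product16)
          op_end <- cursor
        }
        tr[[length(tr) + 1L]] <- tibble::tibble(
          genome_id = genome_id, contig_id = contig_id,
          start = op_start, end = op_end, strand = strand,
          its_len = its_len, len16 = l16, len23 = l23,
          n_sub_16s = n16, n_sub_its = nits, n_sub_23s = n23,
          anomaly = an,
          expected_surviving = an == "none",
          lineage = lineage, assembly_level = assembly_level
        )
      }
      last_anomaly <- anomaly[k]
      if (last_anomaly != "origin_cross") emit(random_dna(config$pad))
      contig <- paste(pieces, collapse = "")
      fasta_path <- file.path(dir, paste0(genome_id, ".fasta"))
      gff_path <- file.path(dir, paste0(genome_id, ".gff"))
      write_fasta(setNames(contig, contig_id), fasta_path)
      write_gff3(dplyr::bind_rows(feats), gff_path)
      manifest[[gi]] <- tibble::tibble(
        genome_id = genome_id, fasta = fasta_path, gff = gff_path,
        assembly_level = assembly_level, lineage = lineage
      )
      truth[[gi]] <- dplyr::bind_rows(tr)
    }
    manifest <- dplyr::bind_rows(manifest)
    truth <- dplyr::bind_rows(truth)
    readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
    readr::write_tsv(truth, file.path(dir, "truth.tsv"))
    jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(structure(
      list(dir = dir, manifest = manifest, truth = truth, config = config),
      class = "rrn_fixture"
    ))
  })
}
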
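#' Read a genomes manifest
#'
#' The manifest is the unit of input for database construction: one row
#' per genome with the paths to its assembly FASTA and GFF3 annotation,
#' its assembly level, and its seven-rank lineage.
#'
#' @param path Path to a TSV with columns `genome_id`, `fasta`, `gff`,
#'   `assembly_level` (`"complete"` or `"incomplete"`) and `lineage`.
#' @return A tibble.
#' @export
read_manifest <- function(path) {
  man <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("genome_id", "fasta", "gff", "assembly_level", "lineage")
  missing <- setdiff(required, names(man))
  if (length(missing)) {
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- !man$assembly_level %in% c("complete", "incomplete")
  if (any(bad)) {
    stop("assembly_level must be 'complete' or 'incomplete' (genome(s): ",
         paste(man$genome_id[bad], collapse = ", "), ")", call. = FALSE)
  }
  man
}

#' Extract quality-checked operons from a set of annotated genomes
#'
#' Runs the extraction stages over every genome in a manifest: read FASTA
#' and GFF3, classify rRNA features and discard partial genes, link 16S
#' and 23S genes into operons, filter oversized-ITS and contig-boundary
#' violations, extract strand-corrected sequences and assign unique
#' operon identifiers.
#'
#' @param manifest A manifest tibble (see [read_manifest()]) or a path to
#'   one.
#' @param max_its Maximum retained ITS length (default 1500 nt).
#' @param canon_16s,canon_23s Canonical gene lengths for partial-gene
#'   coverage (see [classify_rrna_features()]).
#' @return A list with `operons` (tibble including `operon_id` and
#'   `sequence`), `filter_report` (tibble of removals by genome and
#'   reason) and `n_features` (count of classified rRNA features).
#' @export
extract_operons <- function(manifest, max_its = 1500L, canon_16s = 1534L,
                            canon_23s = 2924L) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  feats <- list()
  contigs <- list()
  for (i in seq_len(nrow(manifest))) {
    fa <- read_fasta(manifest$fasta[i])
    gff <- read_gff3(manifest$gff[i])
    gff$genome_id <- manifest$genome_id[i]
    gff$assembly_level <- manifest$assembly_level[i]
    fa$genome_id <- manifest$genome_id[i]
    feats[[i]] <- classify_rrna_features(gff, canon_16s = canon_16s,
                                         canon_23s = canon_23s)
    contigs[[i]] <- fa
  }
  features <- dplyr::bind_rows(feats)
  contigs <- dplyr::bind_rows(contigs)
  linked <- link_operons(features)
  filtered <- filter_operons(linked, contigs, max_its = max_its)
  ops <- filtered$operons
  if (nrow(ops)) {
    ops <- extract_operon_sequence(ops, contigs)
    ops <- assign_operon_ids(ops)
  }
  message("extract: ", nrow(features), " rRNA features, ",
          nrow(linked), " linked operons, ", nrow(ops),
          " after filters (removed: ",
          sum(filtered$report$n %||% 0L), ")")
  list(operons = ops, filter_report = filtered$report,
       n_features = nrow(features))
}

#' Build a non-redundant rRNA operon database
#'
#' The full construction pipeline: operon extraction and filtering
#' ([extract_operons()]), two-phase dereplication in which sequences from
#' complete assemblies are clustered first and sequences from incomplete
#' assemblies are then appended to the representatives and re-clustered
#' ([derep_two_phase()]), cluster taxonomy under the three systems
#' ([cluster_taxonomy()]), and summary statistics. When `out_dir` is
#' given, writes the representative (`nrRep.fasta`) and consensus
#' (`nrCon.fasta`) databases, the full operon FASTA and BED-like TSV, the
#' cluster membership TSV, one taxonomy TSV per system, the filter report
#' and a stats TSV, plus a JSON echo of the configuration.
#'
#' @inheritParams extract_operons
#' @param out_dir Optional output directory.
#' @param id_threshold Dereplication identity threshold (percent, default
#'   99.9).
#' @param consensus Compute consensus sequences (default `TRUE`).
#' @return An object of class `rrn_db`: list with `operons`, `derep`
#'   (an `rrn_derep`), `taxonomy`, `filter_report`, `stats` and `config`.
#' @export
build_rrn_db <- function(manifest, out_dir = NULL, id_threshold = 99.9,
                         max_its = 1500L, canon_16s = 1534L,
                         canon_23s = 2924L, consensus = TRUE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  ext <- extract_operons(manifest, max_its = max_its, canon_16s = canon_16s,
                         canon_23s = canon_23s)
  ops <- ext$operons
  if (nrow(ops) == 0) stop("no operons survived extraction", call. = FALSE)
  seqs <- tibble::tibble(id = ops$operon_id, sequence = ops$sequence,
                         assembly_level = ops$assembly_level)
  complete <- seqs[seqs$assembly_level == "complete", c("id", "sequence")]
  incomplete <- seqs[seqs$assembly_level == "incomplete", c("id", "sequence")]
  if (nrow(complete) == 0) {
    complete <- incomplete
    incomplete <- incomplete[0, ]
  }
  derep <- derep_two_phase(complete, incomplete, threshold = id_threshold,
                           consensus = consensus)
  lineages <- manifest[, c("genome_id", "lineage")]
  taxonomy <- cluster_taxonomy(derep, lineages)
  stats <- tibble::tibble(
    n_genomes = nrow(manifest),
    n_features = ext$n_features,
    n_operons = nrow(ops),
    n_clusters = nrow(derep$clusters),
    reduction = reduction_percent(nrow(ops), nrow(derep$clusters)),
    singleton_fraction = mean(derep$clusters$size == 1),
    species_agreement = species_agreement_fraction(derep, lineages)
  )
  config <- list(id_threshold = id_threshold, max_its = max_its,
                 canon_16s = canon_16s, canon_23s = canon_23s,
                 consensus = consensus)
  db <- structure(
    list(operons = ops, derep = derep, taxonomy = taxonomy,
         filter_report = ext$filter_report, stats = stats,
         lineages = lineages, config = config),
    class = "rrn_db"
  )
  if (!is.null(out_dir)) write_rrn_db(db, out_dir)
  db
}

#' Write a built database to disk
#'
#' @param db An `rrn_db` object from [build_rrn_db()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_rrn_db <- function(db, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ops <- db$operons
  write_fasta(setNames(ops$sequence, ops$operon_id),
              file.path(out_dir, "operons.fasta"))
  readr::write_tsv(
    dplyr::select(ops, "contig_id", "start", "end", "operon_id", "strand",
                  "its_len"),
    file.path(out_dir, "operons.tsv")
  )
  reps <- db$derep$clusters
  rep_seq <- ops$sequence[match(reps$representative_id, ops$operon_id)]
  write_fasta(setNames(rep_seq, reps$representative_id),
              file.path(out_dir, "nrRep.fasta"))
  if (!is.null(reps$consensus)) {
    write_fasta(setNames(reps$consensus, reps$cluster_id),
                file.path(out_dir, "nrCon.fasta"))
  }
  readr::write_tsv(db$derep$members, file.path(out_dir, "membership.tsv"))
  for (system in setdiff(names(db$taxonomy), "cluster_id")) {
    readr::write_tsv(
      setNames(db$taxonomy[, c("cluster_id", system)],
               c("cluster_id", "lineage")),
      file.path(out_dir, paste0("taxonomy_", system, ".tsv"))
    )
  }
  if (nrow(db$filter_report)) {
    readr::write_tsv(db$filter_report, file.path(out_dir, "filter_report.tsv"))
  }
  readr::write_tsv(db$stats, file.path(out_dir, "stats.tsv"))
  jsonlite::write_json(db$config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.rrn_db <- function(x, ...) {
  cat("rRNA operon database\n")
  print(x$stats)
  invisible(x)
}

#' Intragenomic diversity analysis over a manifest or database
#'
#' Convenience wrapper: extracts operons (or reuses a built database),
#' restricts to complete assemblies, computes intragenomic pairwise
#' identities per region, the per-region summary and the cross-region
#' correlation matrix, and optionally writes the long table, summary and
#' per-genome Phylip distance matrices.
#'
#' @param x A manifest path/tibble or an `rrn_db` object.
#' @param out_dir Optional output directory.
#' @param regions Regions to analyse.
#' @param write_matrices Also write one Phylip distance matrix per genome
#'   and region (default `FALSE`).
#' @return A list with `pairs` (the `rrn_diversity` tibble), `summary`
#'   and `correlation`.
#' @export
run_intragenomic_diversity <- function(x, out_dir = NULL, regions = REGIONS,
                                       write_matrices = FALSE) {
  ops <- if (inherits(x, "rrn_db")) x$operons else extract_operons(x)$operons
  ops <- ops[ops$assembly_level == "complete", , drop = FALSE]
  div <- intragenomic_diversity(ops, regions = regions)
  summ <- diversity_summary(div)
  corr <- region_correlation(div)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(tibble::as_tibble(div),
                     file.path(out_dir, "diversity_pairs.tsv"))
    readr::write_tsv(summ, file.path(out_dir, "diversity_summary.tsv"))
    if (write_matrices) {
      for (g in unique(div$genome_id)) {
        for (r in unique(div$region[div$genome_id == g])) {
          m <- distance_matrix(div, g, r)
          rownames(m) <- colnames(m) <- gsub("[|]", "_", rownames(m))
          write_phylip_distmat(
            m, file.path(out_dir, sprintf("distmat_%s_%s.phylip", g, r)))
        }
      }
    }
  }
  list(pairs = div, summary = summ, correlation = corr)
}

#' In-silico PCR evaluation over a built database
#'
#' @param x An `rrn_db` object, or a tibble of sequences (`id`,
#'   `sequence`).
#' @param primers Primer pairs tibble (default [rrn_primers()]).
#' @param out_dir Optional output directory for the predictions and panel
#'   report TSVs.
#' @param use Which database variant to evaluate when `x` is an `rrn_db`:
#'   `"nrRep"` (cluster representatives, default) or `"operons"` (all
#'   sequences).
#' @inheritParams evaluate_primer_panel
#' @return An `rrn_pcr_panel` object.
#' @export
run_pcr <- function(x, primers = rrn_primers(), out_dir = NULL,
                    use = c("nrRep", "operons"), max_mm = 0L,
                    max_len = 10000L) {
  use <- match.arg(use)
  if (inherits(x, "rrn_db")) {
    lineages <- x$lineages
    if (use == "nrRep") {
      ids <- x$derep$clusters$representative_id
      db <- tibble::tibble(
        id = ids,
        sequence = x$operons$sequence[match(ids, x$operons$operon_id)]
      )
    } else {
      db <- tibble::tibble(id = x$operons$operon_id,
                           sequence = x$operons$sequence)
    }
  } else {
    db <- x
    lineages <- NULL
  }
  panel <- evaluate_primer_panel(db, primers = primers, lineages = lineages,
                                 max_mm = max_mm, max_len = max_len)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(panel$coverage, file.path(out_dir, "pcr_coverage.tsv"))
    readr::write_tsv(panel$amplicons, file.path(out_dir, "pcr_amplicons.tsv"))
    readr::write_tsv(panel$lengths, file.path(out_dir, "pcr_lengths.tsv"))
    if (!is.null(panel$misses)) {
      readr::write_tsv(panel$misses, file.path(out_dir, "pcr_misses.tsv"))
    }
  }
  panel
}
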
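# Small in-code fixture builders shared across tests.

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# one-contig genome with operons planted at explicit coordinates;
# returns list(contigs = tibble, features = tibble)
toy_genome <- function(contig_id = "c1", length = 12000, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      contig_id = contig_id,
      sequence = paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                       collapse = ""),
      length = length
    )
  })
}

rrna_feature <- function(contig_id, start, end, strand, product,
                         genome_id = NULL) {
  out <- tibble::tibble(
    contig_id = contig_id, source = "test", type = "rRNA",
    start = as.integer(start), end = as.integer(end), score = NA_real_,
    strand = strand, phase = NA_integer_,
    attributes = paste0("product=", product)
  )
  if (!is.null(genome_id)) out$genome_id <- genome_id
  out
}

# lineage helpers for taxonomy tests
ecoli_lineage <- paste0(
  "k__Bacteria;p__Proteobacteria;c__Gammaproteobacteria;",
  "o__Enterobacterales;f__Enterobacteriaceae;g__Escherichia;",
  "s__Escherichia coli"
)
shigella_lineage <- paste0(
  "k__Bacteria;p__Proteobacteria;c__Gammaproteobacteria;",
  "o__Enterobacterales;f__Enterobacteriaceae;g__Shigella;",
  "s__Shigella flexneri"
)

random_lineage <- function(width = 2) {
  pick <- function(prefix) paste0(prefix, sample.int(width, 1))
  format_lineage(c("Bacteria", pick("P"), pick("C"), pick("O"), pick("F"),
                   pick("G"), pick("S")))
}
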
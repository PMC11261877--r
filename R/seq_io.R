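#' Read a (multi-)FASTA file into a tibble
#'
#' Sequences are uppercased on read so that downstream clustering and primer
#' matching operate on a canonical alphabet; `N` and other IUPAC ambiguity
#' codes are preserved. The contig identifier is the first whitespace-
#' delimited token of the header line.
#'
#' @param path Path to a FASTA file. Lines may wrap at any width.
#' @return A tibble with columns `contig_id`, `sequence` and `length` (nt),
#'   one row per record, in file order. An empty file yields zero rows.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set) %||% character())
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    stop("duplicate contig id(s) in ", path, ": ",
         paste(dups, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    contig_id = ids,
    sequence = as.character(set, use.names = FALSE),
    length = Biostrings::width(set)
  )
}

#' Write sequences to a FASTA file
#'
#' @param x A tibble with columns `contig_id` and `sequence`, or a named
#'   character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (is.data.frame(x)) {
    seqs <- setNames(x$sequence, x$contig_id %||% x$operon_id)
  } else {
    seqs <- x
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named", call. = FALSE)
  }
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a GFF3 annotation file into a tibble
#'
#' Parsing is delegated to [ape::read.gff()]; an embedded `##FASTA` section
#' (as produced by several annotation tools) is split off beforehand and made
#' available as the `"fasta"` attribute of the result. Coordinates are
#' converted from the GFF3 1-based inclusive convention to the package-wide
#' 0-based half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `contig_id`, `source`, `type`, `start`
#'   (0-based), `end` (exclusive), `score`, `strand`, `phase`, `attributes`
#'   (the raw attribute string; see [gff_attr()]). Records whose input start
#'   exceeds their end are dropped with a warning. If the file embeds a
#'   `##FASTA` section, the result carries the parsed sequences as
#'   `attr(x, "fasta")`.
#' @seealso [write_gff3()], [gff_attr()]
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) {
    stop("GFF3 file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  fasta_at <- which(grepl("^##FASTA", lines))[1]
  fasta <- NULL
  if (!is.na(fasta_at)) {
    if (fasta_at < length(lines)) {
      tf <- tempfile(fileext = ".fasta")
      on.exit(unlink(tf), add = TRUE)
      writeLines(lines[(fasta_at + 1L):length(lines)], tf)
      fasta <- read_fasta(tf)
    }
    lines <- lines[seq_len(fasta_at - 1L)]
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0L) {
    out <- tibble::tibble(
      contig_id = character(), source = character(), type = character(),
      start = integer(), end = integer(), score = numeric(),
      strand = character(), phase = integer(), attributes = character()
    )
    attr(out, "fasta") <- fasta
    return(out)
  }
  tg <- tempfile(fileext = ".gff")
  on.exit(unlink(tg), add = TRUE)
  writeLines(c("##gff-version 3", body), tg)
  df <- ape::read.gff(tg, GFF3 = TRUE)
  bad <- df$start > df$end
  if (any(bad)) {
    warning(sum(bad), " GFF3 record(s) with start > end dropped", call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  out <- tibble::tibble(
    contig_id = as.character(df$seqid),
    source = as.character(df$source),
    type = as.character(df$type),
    start = as.integer(df$start) - 1L,
    end = as.integer(df$end),
    score = as.numeric(df$score),
    strand = as.character(df$strand),
    phase = suppressWarnings(as.integer(df$phase)),
    attributes = as.character(df$attributes)
  )
  attr(out, "fasta") <- fasta
  out
}

#' Write features to a GFF3 file
#'
#' The inverse of [read_gff3()]: internal 0-based half-open coordinates are
#' serialized back to 1-based inclusive.
#'
#' @param features Tibble as returned by [read_gff3()].
#' @param path Output path.
#' @param fasta Optional tibble of sequences (`contig_id`, `sequence`) to
#'   embed as a trailing `##FASTA` section.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, fasta = NULL) {
  fmt <- function(x) ifelse(is.na(x), ".", as.character(x))
  rows <- paste(
    fmt(features$contig_id), fmt(features$source %||% NA), fmt(features$type),
    features$start + 1L, features$end, fmt(features$score %||% NA),
    fmt(features$strand), fmt(features$phase %||% NA), fmt(features$attributes),
    sep = "\t"
  )
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines("##gff-version 3", con)
  if (length(rows)) writeLines(rows, con)
  if (!is.null(fasta) && nrow(fasta) > 0) {
    writeLines("##FASTA", con)
    for (i in seq_len(nrow(fasta))) {
      writeLines(paste0(">", fasta$contig_id[i]), con)
      s <- fasta$sequence[i]
      starts <- seq(1L, nchar(s), by = 60L)
      writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
    }
  }
  invisible(path)
}

#' Extract a key from GFF3 attribute strings
#'
#' @param attributes Character vector of raw GFF3 attribute strings
#'   (`key=value` pairs joined by `;`).
#' @param key Attribute key to extract, e.g. `"product"` or `"Name"`.
#' @return Character vector of values (`NA` where the key is absent).
#' @export
gff_attr <- function(attributes, key) {
  vapply(attributes, function(a) {
    if (is.na(a)) return(NA_character_)
    parts <- strsplit(a, ";", fixed = TRUE)[[1]]
    kv <- strsplit(trimws(parts), "=", fixed = TRUE)
    for (p in kv) {
      if (length(p) >= 2 && p[1] == key) {
        return(paste(p[-1], collapse = "="))
      }
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Reverse-complement nucleotide sequences
#'
#' Full IUPAC-aware reverse complement (R<->Y, K<->M, B<->V, D<->H, S, W and
#' N map to themselves). Errors on characters outside the IUPAC nucleotide
#' alphabet.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of reverse-complemented sequences.
#' @export
reverse_complement <- function(x) {
  if (length(x) == 0) return(character())
  as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x)),
    use.names = FALSE
  )
}

#' Write / read a square Phylip distance matrix
#'
#' Square (full, symmetric) Phylip layout: a first line with the matrix
#' dimension, then one line per row holding the row label and all values.
#' Values are serialized with nine decimal places, so a write/read round trip
#' is exact to 1e-9 per cell.
#'
#' @param m Square numeric matrix; row names are used as labels (generated
#'   as `S1..Sn` when absent). Labels must not contain whitespace.
#' @param path Output path.
#' @return `write_phylip_distmat()` returns `path` invisibly;
#'   `read_phylip_distmat()` returns a labelled square matrix.
#' @export
write_phylip_distmat <- function(m, path) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("distance matrix must be square", call. = FALSE)
  }
  labs <- rownames(m) %||% paste0("S", seq_len(nrow(m)))
  if (any(grepl("\\s", labs))) {
    stop("matrix labels must not contain whitespace", call. = FALSE)
  }
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(formatC(labs[i], width = -12), sprintf("%.9f", m[i, ])),
          collapse = " ")
  }, character(1))
  writeLines(c(sprintf("%5d", nrow(m)), rows), path)
  invisible(path)
}

#' @rdname write_phylip_distmat
#' @export
read_phylip_distmat <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) != n + 1L) {
    stop("malformed Phylip distance matrix: ", path, call. = FALSE)
  }
  labs <- character(n)
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    toks <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(toks) != n + 1L) {
      stop("row ", i, " of ", path, " has ", length(toks) - 1L,
           " values, expected ", n, call. = FALSE)
    }
    labs[i] <- toks[1]
    m[i, ] <- as.numeric(toks[-1])
  }
  dimnames(m) <- list(labs, labs)
  m
}
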
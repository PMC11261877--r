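#' Classify rRNA gene features and flag partial genes
#'
#' Scans GFF3 features for annotated rRNA genes, classifies them as 16S,
#' 23S, 5S or other from their `product`/`Name` attributes, computes the
#' coverage of each gene relative to a canonical gene length, and flags
#' genes as partial when their coverage falls below 80 % of that canonical
#' length or when the annotation itself marks them partial (a
#' `partial=true` attribute or a `(partial)` tag in the product).
#'
#' @param features Tibble of GFF3 features as returned by [read_gff3()].
#'   Optional columns `genome_id` and `assembly_level` are carried through.
#' @param canon_16s,canon_23s Canonical 16S / 23S gene lengths (nt) used as
#'   the coverage denominator. Defaults are the observed mean gene lengths
#'   in large genome collections (1534 and 2924 nt).
#' @param partial_coverage Coverage threshold below which a gene is marked
#'   partial (default 0.80).
#' @return Tibble with one row per rRNA feature: `contig_id`, `gene`
#'   (`"16S"`, `"23S"`, `"5S"` or `"other"`), `start`, `end`, `strand`,
#'   `length`, `coverage` (`NA` for 5S/other) and `partial`, plus any
#'   carried-through metadata columns. Unclassifiable rRNA products raise a
#'   warning and are kept with `gene = "other"`.
#' @export
classify_rrna_features <- function(features, canon_16s = 1534L,
                                   canon_23s = 2924L,
                                   partial_coverage = 0.80) {
  rr <- dplyr::filter(features, tolower(.data$type) == "rrna")
  if (nrow(rr) == 0) {
    return(tibble::tibble(
      contig_id = character(), gene = character(), start = integer(),
      end = integer(), strand = character(), length = integer(),
      coverage = numeric(), partial = logical()
    ))
  }
  product <- gff_attr(rr$attributes, "product")
  name <- gff_attr(rr$attributes, "Name")
  label <- paste(ifelse(is.na(product), "", product),
                 ifelse(is.na(name), "", name))
  rrna_like <- grepl("ribosomal RNA|rRNA", label, ignore.case = TRUE)
  gene <- dplyr::case_when(
    grepl("16S", label, ignore.case = TRUE) & rrna_like ~ "16S",
    grepl("23S", label, ignore.case = TRUE) & rrna_like ~ "23S",
    grepl("5S", label, ignore.case = TRUE) & rrna_like ~ "5S",
    TRUE ~ "other"
  )
  if (any(gene == "other")) {
    warning(sum(gene == "other"),
            " rRNA feature(s) with unclassifiable product kept as gene = 'other'",
            call. = FALSE)
  }
  len <- rr$end - rr$start
  coverage <- dplyr::case_when(
    gene == "16S" ~ len / canon_16s,
    gene == "23S" ~ len / canon_23s,
    TRUE ~ NA_real_
  )
  anno_partial <- grepl("partial", label, ignore.case = TRUE) |
    tolower(gff_attr(rr$attributes, "partial") %||% NA_character_) %in% "true"
  partial <- (!is.na(coverage) & coverage < partial_coverage) | anno_partial
  out <- tibble::tibble(
    contig_id = rr$contig_id,
    gene = gene,
    start = rr$start,
    end = rr$end,
    strand = rr$strand,
    length = as.integer(len),
    coverage = coverage,
    partial = partial
  )
  for (col in c("genome_id", "assembly_level")) {
    if (col %in% names(rr)) out[[col]] <- rr[[col]]
  }
  out
}

link_operons_group <- function(df, warn_prefix) {
  plus <- df$strand[1] == "+"
  g16 <- df[df$gene == "16S", , drop = FALSE]
  g23 <- df[df$gene == "23S", , drop = FALSE]
  if (nrow(g16) == 0 || nrow(g23) == 0) return(NULL)
  if (plus) {
    g16 <- g16[order(g16$start), , drop = FALSE]
    g23 <- g23[order(g23$start), , drop = FALSE]
  } else {
    g16 <- g16[order(-g16$end), , drop = FALSE]
    g23 <- g23[order(-g23$end), , drop = FALSE]
  }
  used <- logical(nrow(g23))
  out <- vector("list", nrow(g16))
  for (i in seq_len(nrow(g16))) {
    s16 <- g16[i, ]
    if (plus) {
      cand <- which(!used & g23$start >= s16$start)
      if (length(cand) == 0) next
      pick <- cand[which.min(g23$start[cand])]
      gap <- g23$start[pick] - s16$end
    } else {
      cand <- which(!used & g23$end <= s16$end)
      if (length(cand) == 0) next
      pick <- cand[which.max(g23$end[cand])]
      gap <- s16$start - g23$end[pick]
    }
    if (gap < 0) {
      warning(warn_prefix, ": overlapping 16S/23S annotations near position ",
              s16$start, "; pair rejected", call. = FALSE)
      next
    }
    used[pick] <- TRUE
    s23 <- g23[pick, ]
    out[[i]] <- tibble::tibble(
      s16_start = s16$start, s16_end = s16$end,
      s23_start = s23$start, s23_end = s23$end,
      its_start = if (plus) s16$end else s23$end,
      its_end = if (plus) s23$start else s16$start,
      start = min(s16$start, s23$start),
      end = max(s16$end, s23$end)
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(NULL)
  res$its_len <- res$its_end - res$its_start
  res
}

#' Link 16S and 23S genes into candidate rRNA operons
#'
#' Within each contig and strand, each (non-partial) 16S gene is paired
#' with the nearest unused 23S gene downstream of it in transcription order
#' (greater coordinates on the plus strand, lesser on the minus strand),
#' giving units in the biological 16S-ITS-23S order. Each 23S gene is
#' consumed by at most one 16S; unpaired genes are dropped. The internal
#' transcribed spacer (ITS) is the gap between the two genes. Overlapping
#' 16S/23S annotations (a negative gap) reject the pair with a warning.
#'
#' @param features Tibble of classified rRNA features from
#'   [classify_rrna_features()]. Rows flagged `partial` and genes other
#'   than 16S/23S are ignored.
#' @return Tibble of candidate operons with columns `genome_id` (if
#'   present), `contig_id`, `strand`, `s16_start`, `s16_end`, `s23_start`,
#'   `s23_end`, `its_start`, `its_end`, `its_len`, `start`, `end` (the full
#'   operon interval) and `assembly_level` (if present). All coordinates
#'   0-based half-open.
#' @export
link_operons <- function(features) {
  keep <- features$gene %in% c("16S", "23S")
  if ("partial" %in% names(features)) keep <- keep & !features$partial
  df <- features[keep, , drop = FALSE]
  empty <- tibble::tibble(
    contig_id = character(), strand = character(),
    s16_start = integer(), s16_end = integer(),
    s23_start = integer(), s23_end = integer(),
    its_start = integer(), its_end = integer(), its_len = integer(),
    start = integer(), end = integer()
  )
  if (nrow(df) == 0) return(empty)
  has_genome <- "genome_id" %in% names(df)
  keys <- df[, intersect(c("genome_id", "contig_id", "strand"), names(df)),
             drop = FALSE]
  groups <- split(seq_len(nrow(df)), interaction(keys, drop = TRUE))
  out <- lapply(groups, function(idx) {
    g <- df[idx, , drop = FALSE]
    prefix <- paste0(if (has_genome) paste0(g$genome_id[1], " ") else "",
                     g$contig_id[1], " (", g$strand[1], ")")
    ops <- link_operons_group(g, prefix)
    if (is.null(ops)) return(NULL)
    ops$contig_id <- g$contig_id[1]
    ops$strand <- g$strand[1]
    if (has_genome) ops$genome_id <- g$genome_id[1]
    if ("assembly_level" %in% names(g)) ops$assembly_level <- g$assembly_level[1]
    ops
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(empty)
  front <- intersect(c("genome_id", "contig_id", "strand"), names(res))
  res <- dplyr::relocate(res, dplyr::all_of(front))
  ord <- intersect(c("genome_id", "contig_id", "start"), names(res))
  dplyr::arrange(res, dplyr::across(dplyr::all_of(ord)))
}

#' Quality-filter candidate operons
#'
#' Removes "unlinked" operons, whose ITS is longer than `max_its`
#' (strictly greater: an ITS of exactly `max_its` is retained), and
#' operons whose full interval is not contained within their contig --
#' e.g. annotations wrapping the origin of a circular replicon.
#'
#' @param operons Tibble from [link_operons()].
#' @param assemblies Tibble of contig lengths with columns `contig_id` and
#'   `length` (plus `genome_id` when contig ids repeat across genomes).
#' @param max_its Maximum retained ITS length in nt (default 1500).
#' @return A list with `operons` (the retained rows) and `report`, a
#'   tibble tallying removals by genome and reason (`"unlinked"` or
#'   `"boundary"`).
#' @export
filter_operons <- function(operons, assemblies, max_its = 1500L) {
  by <- intersect(c("genome_id", "contig_id"), names(assemblies))
  by <- intersect(by, names(operons))
  lens <- dplyr::select(assemblies, dplyr::all_of(by),
                        contig_length = dplyr::all_of("length"))
  x <- dplyr::left_join(operons, lens, by = by)
  if (anyNA(x$contig_length)) {
    stop("contig length missing for some operons; check `assemblies`",
         call. = FALSE)
  }
  reason <- dplyr::case_when(
    x$its_len > max_its ~ "unlinked",
    x$start < 0 | x$end > x$contig_length ~ "boundary",
    TRUE ~ NA_character_
  )
  kept <- x[is.na(reason), setdiff(names(x), "contig_length"), drop = FALSE]
  removed <- x[!is.na(reason), , drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  grp <- intersect("genome_id", names(removed))
  report <- dplyr::count(removed, dplyr::across(dplyr::all_of(c(grp, "reason"))),
                         name = "n")
  list(operons = kept, report = report)
}

#' Extract strand-corrected operon sequences
#'
#' Slices each operon's full interval out of its contig; minus-strand
#' operons are reverse-complemented so that every returned sequence reads
#' 16S -> ITS -> 23S in the 5'->3' direction. Region lengths (`len16`,
#' `its_len`, `len23`) are attached so constituent regions can be sliced
#' from the extracted sequence later.
#'
#' @param operons Tibble of filtered operons.
#' @param contigs Tibble of contig sequences (`contig_id`, `sequence`, plus
#'   `genome_id` when needed to disambiguate).
#' @return `operons` with added columns `sequence`, `len16` and `len23`.
#'   An operon extending outside its contig is an error (such operons
#'   should have been removed by [filter_operons()]).
#' @export
extract_operon_sequence <- function(operons, contigs) {
  by <- intersect(intersect(c("genome_id", "contig_id"), names(contigs)),
                  names(operons))
  seqs <- dplyr::select(contigs, dplyr::all_of(by),
                        contig_seq = dplyr::all_of("sequence"))
  x <- dplyr::left_join(operons, seqs, by = by)
  if (anyNA(x$contig_seq)) {
    stop("contig sequence missing for some operons", call. = FALSE)
  }
  if (any(x$start < 0 | x$end > nchar(x$contig_seq))) {
    stop("operon interval outside contig bounds; run filter_operons() first",
         call. = FALSE)
  }
  seq <- substr(x$contig_seq, x$start + 1L, x$end)
  minus <- x$strand == "-"
  if (any(minus)) seq[minus] <- reverse_complement(seq[minus])
  x$sequence <- seq
  x$len16 <- x$s16_end - x$s16_start
  x$len23 <- x$s23_end - x$s23_start
  dplyr::select(x, -"contig_seq")
}

#' Assign unique operon identifiers
#'
#' Identifiers follow the scheme
#' `<genome_id>|<contig_id>|<start>-<end>|<strand>` and are checked for
#' uniqueness across the dataset. [parse_operon_id()] is the exact inverse.
#'
#' @param operons Tibble with columns `genome_id`, `contig_id`, `start`,
#'   `end`, `strand`. Identifier components must not contain `|`.
#' @return `operons` with an added `operon_id` column.
#' @export
assign_operon_ids <- function(operons) {
  comp <- c(operons$genome_id, operons$contig_id)
  if (any(grepl("|", comp, fixed = TRUE))) {
    stop("genome and contig ids must not contain '|'", call. = FALSE)
  }
  ids <- sprintf("%s|%s|%d-%d|%s", operons$genome_id, operons$contig_id,
                 operons$start, operons$end, operons$strand)
  if (anyDuplicated(ids)) {
    stop("operon id collision: ", paste(unique(ids[duplicated(ids)]),
                                        collapse = ", "), call. = FALSE)
  }
  operons$operon_id <- ids
  dplyr::relocate(operons, "operon_id")
}

#' @rdname assign_operon_ids
#' @param ids Character vector of operon identifiers.
#' @return `parse_operon_id()` returns a tibble with the coordinate fields
#'   recovered from the identifiers.
#' @export
parse_operon_id <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  bad <- lengths(parts) != 4
  if (any(bad)) {
    stop("malformed operon id(s): ", paste(ids[bad], collapse = ", "),
         call. = FALSE)
  }
  coords <- vapply(parts, `[[`, character(1), 3)
  se <- strsplit(coords, "-", fixed = TRUE)
  tibble::tibble(
    operon_id = ids,
    genome_id = vapply(parts, `[[`, character(1), 1),
    contig_id = vapply(parts, `[[`, character(1), 2),
    start = as.integer(vapply(se, `[[`, character(1), 1)),
    end = as.integer(vapply(se, `[[`, character(1), 2)),
    strand = vapply(parts, `[[`, character(1), 4)
  )
}
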
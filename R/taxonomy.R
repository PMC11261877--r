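LINEAGE_RANKS <- c("kingdom", "phylum", "class", "order", "family",
                   "genus", "species")
LINEAGE_PREFIXES <- c("k", "p", "c", "o", "f", "g", "s")

#' Parse seven-rank lineage strings
#'
#' Lineages use the seven-rank convention kingdom > phylum > class > order >
#' family > genus > species, serialized as semicolon-separated fields with
#' optional single-letter rank prefixes (`k__Bacteria;p__...;s__...`).
#' Missing trailing ranks are filled as empty; an empty rank above a named
#' one (a gap in the lineage) is an error, as is a lineage with more than
#' seven fields.
#'
#' @param text Character vector of lineage strings.
#' @return A tibble with one row per input and one column per rank.
#' @seealso [format_lineage()]
#' @export
parse_lineage <- function(text) {
  rows <- lapply(text, function(s) {
    if (is.na(s)) s <- ""
    fields <- if (nzchar(trimws(s))) {
      strsplit(s, ";", fixed = TRUE)[[1]]
    } else {
      character(0)
    }
    if (length(fields) > 7) {
      stop("lineage has more than seven ranks: ", s, call. = FALSE)
    }
    fields <- trimws(fields)
    fields <- sub("^[kpcofgsd]__", "", fields)
    fields <- c(fields, rep("", 7 - length(fields)))
    named <- nzchar(fields)
    if (any(named) && any(!named[seq_len(max(which(named)))])) {
      stop("gap in lineage (empty rank above a named rank): ", s,
           call. = FALSE)
    }
    fields
  })
  m <- do.call(rbind, rows)
  colnames(m) <- LINEAGE_RANKS
  tibble::as_tibble(m)
}

#' Format lineages to prefixed seven-rank strings
#'
#' @param x A tibble/data frame with the seven rank columns (as returned by
#'   [parse_lineage()]), or a character vector of seven rank names.
#' @return Character vector of `k__...;p__...;...;s__...` strings; empty
#'   ranks render as bare prefixes.
#' @export
format_lineage <- function(x) {
  if (is.character(x) && is.null(dim(x))) {
    x <- matrix(x, nrow = 1)
  }
  x <- as.matrix(x)
  if (ncol(x) != 7) stop("expected seven ranks", call. = FALSE)
  apply(x, 1, function(r) {
    paste(paste0(LINEAGE_PREFIXES, "__", r), collapse = ";")
  })
}

lineage_matrix <- function(lineages) {
  as.matrix(parse_lineage(lineages))
}

#' Lowest common ancestor of a set of lineages
#'
#' Returns the deepest rank at which every input lineage carries the same
#' (non-empty) name with an identical path above it; deeper ranks are
#' emptied. Disagreement at kingdom yields a fully empty lineage.
#'
#' @param lineages Character vector (multiset) of lineage strings; must be
#'   non-empty.
#' @return A single lineage string.
#' @export
tax_lca <- function(lineages) {
  if (length(lineages) == 0) stop("empty lineage set", call. = FALSE)
  m <- lineage_matrix(lineages)
  out <- rep("", 7)
  for (r in seq_len(7)) {
    u <- unique(m[, r])
    if (length(u) == 1 && nzchar(u)) out[r] <- u else break
  }
  format_lineage(out)
}

#' Lowest rank with strict-majority lineage agreement
#'
#' Scans from species upward and returns the first rank at which some full
#' lineage prefix (the path from kingdom down to that rank) is shared by
#' strictly more than half of the members; deeper ranks are emptied.
#' Majorities are counted over full prefixes, not bare names, so homonymous
#' names under different parents cannot pool votes. Exact 50/50 ties carry
#' no majority and fall through to the next rank up. Members with an empty
#' name at a rank support no prefix at that rank (but still count in the
#' denominator).
#'
#' @inheritParams tax_lca
#' @return A single lineage string (fully empty when no rank reaches a
#'   strict majority).
#' @export
tax_maj <- function(lineages) {
  n <- length(lineages)
  if (n == 0) stop("empty lineage set", call. = FALSE)
  m <- lineage_matrix(lineages)
  for (r in rev(seq_len(7))) {
    named <- nzchar(m[, r])
    if (!any(named)) next
    prefixes <- apply(m[named, seq_len(r), drop = FALSE], 1, paste,
                      collapse = "\x1f")
    counts <- table(prefixes)
    top <- which.max(counts)
    if (counts[top] * 2 > n) {
      out <- rep("", 7)
      out[seq_len(r)] <- strsplit(names(counts)[top], "\x1f", fixed = TRUE)[[1]]
      return(format_lineage(out))
    }
  }
  format_lineage(rep("", 7))
}

#' Cluster-level taxonomy under the three assignment systems
#'
#' Assigns a lineage to every cluster of a dereplication result by each of
#' three systems: `taxRep`, the lineage of the representative's source
#' genome; `taxLCA`, the lowest common ancestor of all members' lineages
#' ([tax_lca()]); and `taxMaj`, the lowest rank with strict-majority
#' agreement ([tax_maj()]). Member genomes are recovered from the operon
#' identifiers (see [parse_operon_id()]).
#'
#' @param derep An `rrn_derep` object (see [greedy_cluster()]).
#' @param genome_lineages Tibble with columns `genome_id` and `lineage`.
#' @param systems Character vector of systems to compute.
#' @return Tibble with `cluster_id` and one column per requested system.
#'   A member genome missing from `genome_lineages` is an error.
#' @export
cluster_taxonomy <- function(derep, genome_lineages,
                             systems = c("taxRep", "taxLCA", "taxMaj")) {
  systems <- match.arg(systems, several.ok = TRUE)
  members <- derep$members
  gid <- parse_operon_id(members$member_id)$genome_id
  lin <- genome_lineages$lineage[match(gid, genome_lineages$genome_id)]
  if (anyNA(lin)) {
    stop("lineage missing for genome(s): ",
         paste(unique(gid[is.na(lin)]), collapse = ", "), call. = FALSE)
  }
  members$lineage <- lin
  by_cluster <- split(members$lineage, members$cluster_id)
  out <- tibble::tibble(cluster_id = derep$clusters$cluster_id)
  if ("taxRep" %in% systems) {
    rep_gid <- parse_operon_id(derep$clusters$representative_id)$genome_id
    rep_lin <- genome_lineages$lineage[match(rep_gid, genome_lineages$genome_id)]
    if (anyNA(rep_lin)) {
      stop("lineage missing for representative genome(s): ",
           paste(unique(rep_gid[is.na(rep_lin)]), collapse = ", "),
           call. = FALSE)
    }
    out$taxRep <- format_lineage(as.matrix(parse_lineage(rep_lin)))
  }
  if ("taxLCA" %in% systems) {
    out$taxLCA <- unname(vapply(by_cluster[out$cluster_id], tax_lca,
                                character(1)))
  }
  if ("taxMaj" %in% systems) {
    out$taxMaj <- unname(vapply(by_cluster[out$cluster_id], tax_maj,
                                character(1)))
  }
  out
}

#' Fraction of clusters with full species-level agreement
#'
#' @param derep An `rrn_derep` object.
#' @param genome_lineages Tibble with `genome_id` and `lineage`.
#' @return Percentage of clusters whose members all share one identical
#'   species-level lineage.
#' @export
species_agreement_fraction <- function(derep, genome_lineages) {
  members <- derep$members
  if (nrow(members) == 0) return(numeric(0))
  gid <- parse_operon_id(members$member_id)$genome_id
  lin <- genome_lineages$lineage[match(gid, genome_lineages$genome_id)]
  if (anyNA(lin)) {
    stop("lineage missing for genome(s): ",
         paste(unique(gid[is.na(lin)]), collapse = ", "), call. = FALSE)
  }
  canon <- format_lineage(as.matrix(parse_lineage(lin)))
  agree <- vapply(split(canon, members$cluster_id),
                  function(x) length(unique(x)) == 1, logical(1))
  100 * mean(agree)
}

#' Phylum-level composition of a set of lineages
#'
#' @param lineages Character vector of lineage strings.
#' @return Tibble with `phylum`, `count` and `percent` (summing to 100),
#'   sorted by decreasing count. Lineages with an empty phylum are bucketed
#'   as `"unclassified"`. Empty input yields an empty tibble.
#' @export
phylum_composition <- function(lineages) {
  if (length(lineages) == 0) {
    return(tibble::tibble(phylum = character(), count = integer(),
                          percent = numeric()))
  }
  phyla <- lineage_matrix(lineages)[, "phylum"]
  phyla[!nzchar(phyla)] <- "unclassified"
  tab <- sort(table(phyla), decreasing = TRUE)
  tibble::tibble(
    phylum = names(tab),
    count = as.integer(tab),
    percent = 100 * as.integer(tab) / length(phyla)
  )
}
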
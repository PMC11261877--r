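REGIONS <- c("rrn", "16S", "ITS", "23S")

# slice a constituent region out of a transcription-oriented operon sequence
region_subseq <- function(sequence, len16, its_len, len23, region) {
  switch(region,
    "rrn" = sequence,
    "16S" = substr(sequence, 1L, len16),
    "ITS" = if (its_len > 0) {
      substr(sequence, len16 + 1L, len16 + its_len)
    } else {
      ""
    },
    "23S" = substr(sequence, len16 + its_len + 1L, len16 + its_len + len23),
    stop("unknown region: ", region, call. = FALSE)
  )
}

#' Intragenomic pairwise identities per region
#'
#' For every genome contributing at least two operons, computes pairwise
#' distances (SNVs per 100 comparable nucleotides, see
#' [pairwise_distance()]) between all operon copies, for the whole operon
#' and each constituent region (16S, ITS, 23S) sliced from the
#' transcription-oriented operon sequence. Genomes with fewer than two
#' operons are skipped with a message.
#'
#' @param operons Tibble of extracted operons carrying `genome_id`,
#'   `operon_id`, `sequence`, `len16`, `its_len`, `len23` (see
#'   [extract_operon_sequence()] and [assign_operon_ids()]).
#' @param regions Regions to compare (default all four).
#' @param band Alignment band passed down to [pairwise_distance()].
#' @return An object of class `rrn_diversity`: a long tibble with columns
#'   `genome_id`, `region`, `id_a`, `id_b`, `distance`, `identity`, one row
#'   per region and unordered operon pair. Supports [tidy()], [glance()]
#'   and [autoplot()].
#' @export
intragenomic_diversity <- function(operons, regions = REGIONS, band = NULL) {
  regions <- match.arg(regions, REGIONS, several.ok = TRUE)
  by_genome <- split(seq_len(nrow(operons)), operons$genome_id)
  skipped <- names(by_genome)[vapply(by_genome, length, 1L) < 2]
  if (length(skipped)) {
    message(length(skipped), " genome(s) with < 2 operons skipped: ",
            paste(head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ..." else "")
  }
  rows <- list()
  for (g in names(by_genome)) {
    idx <- by_genome[[g]]
    if (length(idx) < 2) next
    ops <- operons[idx, , drop = FALSE]
    prs <- utils::combn(seq_len(nrow(ops)), 2)
    for (region in regions) {
      rseq <- vapply(seq_len(nrow(ops)), function(i) {
        region_subseq(ops$sequence[i], ops$len16[i], ops$its_len[i],
                      ops$len23[i], region)
      }, character(1))
      d <- vapply(seq_len(ncol(prs)), function(k) {
        a <- rseq[prs[1, k]]; b <- rseq[prs[2, k]]
        if (!nzchar(a) || !nzchar(b)) return(NA_real_)
        if (a == b) return(0) else pairwise_distance(a, b, band = band)
      }, numeric(1))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        genome_id = g,
        region = region,
        id_a = ops$operon_id[prs[1, ]],
        id_b = ops$operon_id[prs[2, ]],
        distance = d,
        identity = identity_from_distance(d)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(genome_id = character(), region = character(),
                          id_a = character(), id_b = character(),
                          distance = numeric(), identity = numeric())
  }
  class(out) <- c("rrn_diversity", class(out))
  out
}

#' Per-region summaries of intragenomic diversity
#'
#' Pairwise identities are pooled across genomes (not averaged per
#' genome); `fraction_genomes_diverse` is the fraction of multi-copy
#' genomes showing any pairwise identity below 100 for that region.
#'
#' @param diversity An `rrn_diversity` tibble from
#'   [intragenomic_diversity()].
#' @return Tibble with one row per region: `region`, `n_genomes`,
#'   `n_pairs`, `mean`, `median`, `sd`, `cv` (of identities;
#'   `cv = 100 * sd / mean`) and `fraction_genomes_diverse`.
#' @export
diversity_summary <- function(diversity) {
  div <- tibble::as_tibble(diversity)
  div <- div[!is.na(div$distance), , drop = FALSE]
  dplyr::summarise(
    dplyr::group_by(div, .data$region),
    n_genomes = dplyr::n_distinct(.data$genome_id),
    n_pairs = dplyr::n(),
    mean = mean(.data$identity),
    median = median(.data$identity),
    sd = sd(.data$identity),
    cv = ifelse(mean(.data$identity) > 0,
                100 * sd(.data$identity) / mean(.data$identity), NA_real_),
    fraction_genomes_diverse =
      dplyr::n_distinct(.data$genome_id[.data$identity < 100]) /
      dplyr::n_distinct(.data$genome_id),
    .groups = "drop"
  )
}

#' Pearson correlation of identities between regions
#'
#' Identity values from the same operon pair are matched across regions by
#' the (genome, operon pair) key, and Pearson correlations are computed for
#' every region pair. Correlations over fewer than three complete pairs,
#' or with zero variance in either margin, are reported as `NA`.
#'
#' @inheritParams diversity_summary
#' @return A symmetric correlation matrix over the regions present.
#' @export
region_correlation <- function(diversity) {
  div <- tibble::as_tibble(diversity)
  wide <- tidyr::pivot_wider(
    div,
    id_cols = c("genome_id", "id_a", "id_b"),
    names_from = "region", values_from = "identity"
  )
  regions <- intersect(REGIONS, names(wide))
  m <- matrix(NA_real_, length(regions), length(regions),
              dimnames = list(regions, regions))
  for (i in seq_along(regions)) {
    for (j in seq_along(regions)) {
      x <- wide[[regions[i]]]
      y <- wide[[regions[j]]]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) >= 3 && sd(x[ok]) > 0 && sd(y[ok]) > 0) {
        m[i, j] <- cor(x[ok], y[ok])
      }
    }
  }
  m
}

#' Square distance matrix for one genome and region
#'
#' @inheritParams diversity_summary
#' @param genome_id,region The genome and region to extract.
#' @return A labelled symmetric matrix of distances (SNVs per 100
#'   nucleotides, zero diagonal), suitable for [write_phylip_distmat()].
#' @export
distance_matrix <- function(diversity, genome_id, region) {
  div <- tibble::as_tibble(diversity)
  div <- div[div$genome_id == genome_id & div$region == region, , drop = FALSE]
  if (nrow(div) == 0) {
    stop("no pairs for genome ", genome_id, ", region ", region,
         call. = FALSE)
  }
  labs <- sort(unique(c(div$id_a, div$id_b)))
  m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (k in seq_len(nrow(div))) {
    m[div$id_a[k], div$id_b[k]] <- div$distance[k]
    m[div$id_b[k], div$id_a[k]] <- div$distance[k]
  }
  m
}
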
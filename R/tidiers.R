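#' Tidy a dereplication result
#'
#' @param x An `rrn_derep` object.
#' @param ... Unused.
#' @return The membership tibble joined with cluster size and
#'   representative id: one row per (cluster, member).
#' @export
tidy.rrn_derep <- function(x, ...) {
  dplyr::left_join(
    x$members,
    dplyr::select(x$clusters, "cluster_id", "representative_id", "size"),
    by = "cluster_id"
  )
}

#' One-row summary of a dereplication result
#'
#' @param x An `rrn_derep` object.
#' @param ... Unused.
#' @return Tibble with `n_input`, `n_clusters`, `reduction` (percent),
#'   `singleton_fraction`, `max_cluster_size` and `threshold`.
#' @export
glance.rrn_derep <- function(x, ...) {
  tibble::tibble(
    n_input = x$n_input,
    n_clusters = nrow(x$clusters),
    reduction = reduction_percent(x$n_input, nrow(x$clusters)),
    singleton_fraction = mean(x$clusters$size == 1),
    max_cluster_size = max(x$clusters$size),
    threshold = x$threshold
  )
}

#' Plot the cluster size distribution of a dereplication result
#'
#' @param object An `rrn_derep` object.
#' @param ... Unused.
#' @return A ggplot: number of clusters by cluster size.
#' @export
autoplot.rrn_derep <- function(object, ...) {
  ggplot2::ggplot(object$clusters, ggplot2::aes(x = .data$size)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "operons per NR cluster", y = "clusters") +
    ggplot2::theme_minimal()
}

#' @export
tidy.rrn_diversity <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of intragenomic diversity
#'
#' @param x An `rrn_diversity` tibble.
#' @param ... Unused.
#' @return Tibble with the pooled mean identity, the number of multi-copy
#'   genomes and pairs, and the fraction of genomes with whole-operon
#'   diversity.
#' @export
glance.rrn_diversity <- function(x, ...) {
  s <- diversity_summary(x)
  rrn <- s[s$region == "rrn", , drop = FALSE]
  tibble::tibble(
    n_genomes = if (nrow(rrn)) rrn$n_genomes else 0L,
    n_pairs = if (nrow(rrn)) rrn$n_pairs else 0L,
    mean_identity_rrn = if (nrow(rrn)) rrn$mean else NA_real_,
    fraction_genomes_diverse = if (nrow(rrn)) {
      rrn$fraction_genomes_diverse
    } else {
      NA_real_
    }
  )
}

#' Plot pooled intragenomic identity distributions per region
#'
#' Pairwise identities identified as outliers by the interquartile-range
#' rule (below Q1 - 1.5 IQR or above Q3 + 1.5 IQR, per region) can be
#' trimmed for readability; trimming affects the plot only, never any
#' statistic.
#'
#' @param object An `rrn_diversity` tibble.
#' @param trim_outliers Apply the IQR rule before plotting (default
#'   `FALSE`).
#' @param ... Unused.
#' @return A ggplot of identity histograms, faceted by region.
#' @export
autoplot.rrn_diversity <- function(object, trim_outliers = FALSE, ...) {
  df <- tibble::as_tibble(object)
  df <- df[!is.na(df$identity), , drop = FALSE]
  if (trim_outliers) {
    df <- dplyr::filter(
      dplyr::group_by(df, .data$region),
      {
        q <- stats::quantile(.data$identity, c(0.25, 0.75))
        iqr <- q[2] - q[1]
        .data$identity >= q[1] - 1.5 * iqr & .data$identity <= q[2] + 1.5 * iqr
      }
    )
    df <- dplyr::ungroup(df)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$identity)) +
    ggplot2::geom_histogram(bins = 50) +
    ggplot2::facet_wrap(~region, scales = "free_y") +
    ggplot2::labs(x = "pairwise identity (%)", y = "operon pairs") +
    ggplot2::theme_minimal()
}

#' @export
tidy.rrn_pcr_panel <- function(x, ...) {
  x$coverage
}

#' @export
glance.rrn_pcr_panel <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$coverage),
    n_sequences = x$coverage$n_total[1],
    min_coverage = min(x$coverage$coverage),
    max_coverage = max(x$coverage$coverage)
  )
}

#' Plot primer panel coverage and amplicon lengths
#'
#' @param object An `rrn_pcr_panel` object.
#' @param what `"coverage"` (default) or `"lengths"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rrn_pcr_panel <- function(object, what = c("coverage", "lengths"),
                                   ...) {
  what <- match.arg(what)
  if (what == "coverage") {
    ggplot2::ggplot(object$coverage,
                    ggplot2::aes(x = .data$name, y = .data$coverage)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = NULL, y = "database coverage (%)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$amplicons,
                    ggplot2::aes(x = .data$name, y = .data$length)) +
      ggplot2::geom_boxplot() +
      ggplot2::labs(x = NULL, y = "predicted amplicon length (nt)") +
      ggplot2::theme_minimal()
  }
}

#' @export
tidy.rrn_db <- function(x, ...) {
  tidy(x$derep)
}

#' @export
glance.rrn_db <- function(x, ...) {
  x$stats
}
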
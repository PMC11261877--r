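#' Sort sequences by decreasing length
#'
#' Greedy centroid clustering is order-dependent; sorting by decreasing
#' length first guarantees that the longest sequence in each cluster founds
#' it and therefore becomes its representative. Length ties are broken by
#' lexicographic id so the order (and hence the clustering) is fully
#' deterministic.
#'
#' @param seqs Tibble with columns `id` and `sequence`.
#' @return The same tibble, reordered.
#' @export
sort_by_length <- function(seqs) {
  dplyr::arrange(seqs, dplyr::desc(nchar(.data$sequence)), .data$id)
}

# containment cutoff for the k-mer prescreen: a pair at >= `threshold`
# percent identity cannot lose more than ~k substitutions' worth of k-mers
# per edit; the factor-2 margin also absorbs edits falling as indels.
prescreen_cutoff <- function(threshold, k) {
  max(0, 1 - 2 * k * (1 - threshold / 100) - 0.05)
}

#' Greedy length-sorted centroid clustering
#'
#' Scans sequences in their given order (use [sort_by_length()] first).
#' Each sequence joins the existing centroid to which its ends-free global
#' alignment identity is highest, provided that identity meets the
#' threshold; otherwise it founds a new cluster with itself as centroid and
#' representative. Because input is length-sorted, the representative of
#' every cluster is its longest member.
#'
#' A k-mer containment prescreen (k = 12) skips alignments against
#' centroids that share too few k-mers to possibly reach the threshold;
#' it is conservative at the high identity thresholds used for
#' dereplication and disables itself automatically at low thresholds.
#'
#' @param seqs Tibble with columns `id` and `sequence`, pre-sorted.
#' @param threshold Percent identity threshold in (0, 100]; default 99.9,
#'   the conventional near-duplicate dereplication radius for rRNA operons.
#' @param band Alignment band half-width passed to [align_pair()].
#' @param consensus If `TRUE` (default), compute a column-majority
#'   consensus sequence per cluster (see [consensus_sequence()]).
#' @param prefilter Enable the k-mer prescreen (default `TRUE`).
#' @return An object of class `rrn_derep`: a list with `clusters` (tibble:
#'   `cluster_id`, `representative_id`, `size`, `consensus`), `members`
#'   (tibble: `cluster_id`, `member_id`, `identity_to_rep`,
#'   `is_representative`), `threshold` and `n_input`. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
greedy_cluster <- function(seqs, threshold = 99.9, band = NULL,
                           consensus = TRUE, prefilter = TRUE) {
  stopifnot(is.numeric(threshold), threshold > 0, threshold <= 100)
  n <- nrow(seqs)
  cent_seq <- character(0)
  cent_kmers <- list()
  cent_of <- integer(n)      # cluster index per input sequence
  ident <- numeric(n)
  k <- 12L
  cutoff <- prescreen_cutoff(threshold, k)
  use_prefilter <- prefilter && cutoff > 0
  for (i in seq_len(n)) {
    s <- seqs$sequence[i]
    best_id <- -1
    best_c <- 0L
    exact <- match(s, cent_seq)
    if (!is.na(exact)) {
      best_id <- 100
      best_c <- exact
    } else {
      skm <- if (use_prefilter) kmer_set_cpp(s, k) else NULL
      for (ci in seq_along(cent_seq)) {
        if (use_prefilter && length(skm) && length(cent_kmers[[ci]]) &&
            kmer_containment_sorted_cpp(skm, cent_kmers[[ci]]) < cutoff) {
          next
        }
        idv <- pairwise_identity(s, cent_seq[ci], band = band)
        if (idv >= threshold && idv > best_id) {
          best_id <- idv
          best_c <- ci
        }
      }
    }
    if (best_c > 0L) {
      cent_of[i] <- best_c
      ident[i] <- best_id
    } else {
      cent_seq <- c(cent_seq, s)
      if (use_prefilter) {
        cent_kmers[[length(cent_seq)]] <- skm %||% kmer_set_cpp(s, k)
      }
      cent_of[i] <- length(cent_seq)
      ident[i] <- 100
    }
  }
  rep_idx <- match(seq_along(cent_seq), cent_of)  # founder = first member
  cluster_id <- sprintf("NR%06d", seq_along(cent_seq))
  members <- tibble::tibble(
    cluster_id = cluster_id[cent_of],
    member_id = seqs$id,
    identity_to_rep = ident,
    is_representative = seq_len(n) %in% rep_idx
  )
  clusters <- tibble::tibble(
    cluster_id = cluster_id,
    representative_id = seqs$id[rep_idx],
    size = tabulate(cent_of, nbins = length(cent_seq))
  )
  if (consensus) {
    clusters$consensus <- vapply(seq_along(cent_seq), function(ci) {
      mem <- seqs$sequence[cent_of == ci]
      if (length(mem) == 1L) return(mem)
      consensus_sequence(mem, representative = cent_seq[ci], band = band)
    }, character(1))
  }
  structure(
    list(clusters = clusters, members = members,
         threshold = threshold, n_input = n),
    class = "rrn_derep"
  )
}

#' Augment an existing clustering with new sequences
#'
#' Implements the second phase of two-phase database construction: the
#' representatives of an existing clustering (built from complete-assembly
#' sequences) are pooled with new sequences (from incomplete assemblies),
#' re-sorted by length, and re-clustered. A new sequence can therefore only
#' found a cluster if it is below the identity threshold to every retained
#' centroid, i.e. if it expands on the existing sequence diversity.
#'
#' @param existing_reps Tibble (`id`, `sequence`) of phase-1 representative
#'   sequences, or an `rrn_derep` object together with `seqs` to look the
#'   representatives up in.
#' @param new_seqs Tibble (`id`, `sequence`) of sequences to append.
#' @inheritParams greedy_cluster
#' @return An `rrn_derep` object over representatives plus new sequences.
#' @export
augment_clusters <- function(existing_reps, new_seqs, threshold = 99.9,
                             band = NULL, consensus = TRUE) {
  combined <- dplyr::bind_rows(
    existing_reps[, c("id", "sequence")],
    new_seqs[, c("id", "sequence")]
  )
  if (anyDuplicated(combined$id)) {
    stop("duplicate sequence ids across phases", call. = FALSE)
  }
  greedy_cluster(sort_by_length(combined), threshold = threshold,
                 band = band, consensus = consensus)
}

#' Column-majority consensus of a cluster
#'
#' Builds a star alignment of every member against the representative (the
#' longest member when not given explicitly) and takes, per column, the
#' most frequent symbol. Columns in which gaps hold the majority are
#' dropped; base ties are broken in the fixed order A < C < G < T. For
#' single-member clusters the consensus is the member itself.
#'
#' @param members Character vector of member sequences.
#' @param representative The reference sequence for the star alignment;
#'   defaults to the longest member (first on ties).
#' @param band Alignment band passed to [align_pair()].
#' @return The consensus sequence.
#' @export
consensus_sequence <- function(members, representative = NULL, band = NULL) {
  if (length(members) == 0) stop("empty cluster", call. = FALSE)
  if (is.null(representative)) {
    representative <- members[which.max(nchar(members))]
  }
  if (length(members) == 1L && members[1] == representative) {
    return(representative)
  }
  L <- nchar(representative)
  symbols <- c("A", "C", "G", "T", "N", "-")
  votes <- matrix(0L, nrow = L, ncol = length(symbols),
                  dimnames = list(NULL, symbols))
  # insertion columns relative to the representative, keyed by the
  # representative position they follow (0 = before the first base)
  insertions <- list()
  n_members <- length(members)
  add_vote <- function(pos, sym) {
    col <- match(sym, symbols)
    if (is.na(col)) col <- match("N", symbols)
    votes[pos, col] <<- votes[pos, col] + 1L
  }
  for (mem in members) {
    if (mem == representative) {
      chars <- strsplit(representative, "", fixed = TRUE)[[1]]
      for (p in seq_len(L)) add_vote(p, chars[p])
      next
    }
    aln <- align_pair(representative, mem, band = band)
    ra <- strsplit(aln$a_aln, "", fixed = TRUE)[[1]]
    ma <- strsplit(aln$b_aln, "", fixed = TRUE)[[1]]
    covered <- logical(L)
    rpos <- aln$a_start  # 0-based count of rep bases consumed
    ins_i <- 0L
    for (cc in seq_along(ra)) {
      if (ra[cc] != "-") {
        rpos <- rpos + 1L
        ins_i <- 0L
        covered[rpos] <- TRUE
        add_vote(rpos, ma[cc])
      } else {
        ins_i <- ins_i + 1L
        key <- sprintf("%d.%d", rpos, ins_i)
        ins <- insertions[[key]] %||% setNames(integer(length(symbols)), symbols)
        sym <- if (ma[cc] %in% symbols) ma[cc] else "N"
        ins[sym] <- ins[sym] + 1L
        insertions[[key]] <- ins
      }
    }
    # representative positions outside the member's aligned core count as gaps
    for (p in which(!covered)) add_vote(p, "-")
  }
  pick <- function(v) {
    # v: named counts over A C G T N -
    if (v[["-"]] * 2L > n_members) return("")
    bases <- v[c("A", "C", "G", "T", "N")]
    names(bases)[which.max(bases)]  # which.max keeps the fixed tie order
  }
  out <- character(0)
  emit_ins <- function(after) {
    keys <- names(insertions)
    if (is.null(keys)) return(character(0))
    sel <- keys[startsWith(keys, paste0(after, "."))]
    if (length(sel) == 0) return(character(0))
    sel <- sel[order(as.integer(sub("^\\d+\\.", "", sel)))]
    vapply(sel, function(kk) {
      v <- insertions[[kk]]
      gaps <- n_members - sum(v)   # members lacking the insertion
      if (gaps * 2L > n_members) return("")
      b <- v[c("A", "C", "G", "T", "N")]
      names(b)[which.max(b)]
    }, character(1), USE.NAMES = FALSE)
  }
  out <- c(out, emit_ins(0L))
  for (p in seq_len(L)) {
    out <- c(out, pick(votes[p, ]))
    out <- c(out, emit_ins(p))
  }
  paste(out, collapse = "")
}

#' Size reduction achieved by dereplication
#'
#' @param n_full Number of sequences before dereplication (> 0).
#' @param n_nr Number of non-redundant clusters after dereplication.
#' @return Percent reduction, `100 * (1 - n_nr / n_full)`, rounded to one
#'   decimal place.
#' @export
reduction_percent <- function(n_full, n_nr) {
  if (any(n_full == 0)) stop("n_full must be positive", call. = FALSE)
  round(100 * (1 - n_nr / n_full), 1)
}

#' Two-phase dereplication of complete and incomplete assemblies
#'
#' Phase 1 clusters sequences from complete assemblies; phase 2 appends
#' sequences from incomplete assemblies to the phase-1 representatives and
#' re-clusters, so incomplete-assembly sequences are only retained when
#' they expand on the diversity already captured. Phase-1 members are
#' re-attached to the final cluster their representative landed in, and
#' identities to the final representative are recomputed.
#'
#' @param complete_seqs Tibble (`id`, `sequence`) from complete assemblies.
#' @param incomplete_seqs Tibble (`id`, `sequence`) from incomplete
#'   assemblies; may have zero rows, in which case the result is the
#'   phase-1 clustering.
#' @inheritParams greedy_cluster
#' @return An `rrn_derep` object over all input sequences.
#' @export
derep_two_phase <- function(complete_seqs, incomplete_seqs = NULL,
                            threshold = 99.9, band = NULL, consensus = TRUE) {
  phase1 <- greedy_cluster(sort_by_length(complete_seqs),
                           threshold = threshold, band = band,
                           consensus = FALSE)
  if (is.null(incomplete_seqs) || nrow(incomplete_seqs) == 0) {
    if (consensus) {
      phase1 <- add_consensus(phase1, complete_seqs, band = band)
    }
    return(phase1)
  }
  reps <- tibble::tibble(
    id = phase1$clusters$representative_id,
    sequence = complete_seqs$sequence[match(phase1$clusters$representative_id,
                                            complete_seqs$id)]
  )
  phase2 <- greedy_cluster(sort_by_length(dplyr::bind_rows(reps, incomplete_seqs)),
                           threshold = threshold, band = band,
                           consensus = FALSE)
  all_seqs <- dplyr::bind_rows(complete_seqs, incomplete_seqs)
  # expand phase-1 representatives back into their full memberships
  p1_members <- split(phase1$members$member_id, phase1$members$cluster_id)
  p1_cluster_of_rep <- setNames(names(p1_members), phase1$clusters$representative_id)
  expanded <- lapply(seq_len(nrow(phase2$members)), function(i) {
    mid <- phase2$members$member_id[i]
    cid <- phase2$members$cluster_id[i]
    if (mid %in% names(p1_cluster_of_rep)) {
      tibble::tibble(cluster_id = cid,
                     member_id = p1_members[[p1_cluster_of_rep[[mid]]]],
                     p1_rep = mid)
    } else {
      tibble::tibble(cluster_id = cid, member_id = mid,
                     p1_rep = NA_character_)
    }
  })
  members <- dplyr::bind_rows(expanded)
  clusters <- phase2$clusters
  rep_seq <- all_seqs$sequence[match(clusters$representative_id, all_seqs$id)]
  mem_seq <- all_seqs$sequence[match(members$member_id, all_seqs$id)]
  final_rep <- clusters$representative_id[match(members$cluster_id,
                                                clusters$cluster_id)]
  crep <- rep_seq[match(members$cluster_id, clusters$cluster_id)]
  # identities measured during either phase are reused when the reference
  # representative is unchanged; only re-parented members are re-aligned
  p1_key <- paste(phase1$members$member_id)
  p1_ident <- setNames(phase1$members$identity_to_rep, p1_key)
  p2_ident <- setNames(phase2$members$identity_to_rep, phase2$members$member_id)
  members$identity_to_rep <- vapply(seq_len(nrow(members)), function(i) {
    mid <- members$member_id[i]
    if (mem_seq[i] == crep[i]) return(100)
    if (!is.na(members$p1_rep[i]) && members$p1_rep[i] == final_rep[i]) {
      return(unname(p1_ident[[mid]]))
    }
    if (is.na(members$p1_rep[i]) && mid %in% names(p2_ident)) {
      return(unname(p2_ident[[mid]]))
    }
    pairwise_identity(mem_seq[i], crep[i], band = band)
  }, numeric(1))
  members$p1_rep <- NULL
  members$is_representative <- members$member_id == clusters$representative_id[
    match(members$cluster_id, clusters$cluster_id)]
  clusters$size <- as.integer(table(members$cluster_id)[clusters$cluster_id])
  out <- structure(
    list(clusters = clusters, members = members,
         threshold = threshold, n_input = nrow(all_seqs)),
    class = "rrn_derep"
  )
  if (consensus) out <- add_consensus(out, all_seqs, band = band)
  out
}

# attach column-majority consensus sequences to an rrn_derep object
add_consensus <- function(derep, seqs, band = NULL) {
  mem_by_cluster <- split(derep$members$member_id, derep$members$cluster_id)
  derep$clusters$consensus <- vapply(seq_len(nrow(derep$clusters)), function(i) {
    cl <- derep$clusters$cluster_id[i]
    mem <- seqs$sequence[match(mem_by_cluster[[cl]], seqs$id)]
    rep_seq <- seqs$sequence[match(derep$clusters$representative_id[i], seqs$id)]
    if (length(mem) == 1L) return(mem)
    consensus_sequence(mem, representative = rep_seq, band = band)
  }, character(1))
  derep
}

#' @export
print.rrn_derep <- function(x, ...) {
  cat("Greedy centroid clustering (", x$threshold, "% identity)\n", sep = "")
  cat("  sequences: ", x$n_input, "\n", sep = "")
  cat("  clusters:  ", nrow(x$clusters),
      " (reduction ", reduction_percent(x$n_input, nrow(x$clusters)), "%)\n",
      sep = "")
  cat("  singletons: ", sum(x$clusters$size == 1), "\n", sep = "")
  invisible(x)
}
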
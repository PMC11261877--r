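# IUPAC nucleotide codes as 4-bit sets over (A, C, G, T)
IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

iupac_encode <- function(x, what = "sequence") {
  v <- IUPAC_BITS[strsplit(x, "", fixed = TRUE)[[1]]]
  if (anyNA(v)) {
    stop("non-IUPAC character in ", what, ": ", x, call. = FALSE)
  }
  unname(v)
}

#' Expand an IUPAC string into all concrete sequences
#'
#' @param x A single IUPAC nucleotide string.
#' @return Character vector of all unambiguous (A/C/G/T) sequences the
#'   string denotes.
#' @export
iupac_expand <- function(x) {
  sets <- lapply(iupac_encode(x, "primer"), function(b) {
    c("A", "C", "G", "T")[bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L]
  })
  apply(expand.grid(sets, stringsAsFactors = FALSE), 1, paste, collapse = "")
}

#' Mismatches between a degenerate primer and a template window
#'
#' A position matches when the template base is a concrete A/C/G/T
#' contained in the primer code's expansion set (e.g. primer `R` matches
#' template `A` or `G`). An ambiguous template base -- including `N` --
#' matches nothing, so runs of `N` cannot fabricate primer sites.
#'
#' @param primer_window IUPAC primer string.
#' @param template_window Template window of the same length.
#' @return Count of mismatching positions.
#' @export
iupac_match_count <- function(primer_window, template_window) {
  if (nchar(primer_window) != nchar(template_window)) {
    stop("primer and template windows must have equal length", call. = FALSE)
  }
  p <- iupac_encode(primer_window, "primer")
  t <- iupac_encode(template_window, "template")
  concrete <- t %in% c(1L, 2L, 4L, 8L)
  sum(!(concrete & bitwAnd(p, t) > 0L))
}

#' Find degenerate-primer binding sites on one strand
#'
#' Slides the primer along the given strand of the template and reports
#' every window whose IUPAC-aware mismatch count (see
#' [iupac_match_count()]) does not exceed `max_mm`. Callers handle strand
#' logic; see [predict_amplicons()].
#'
#' @param template Template sequence (A/C/G/T/N...).
#' @param primer IUPAC primer string (5'->3' on the scanned strand).
#' @param max_mm Maximum allowed mismatches (default 0, exact IUPAC-aware
#'   matching).
#' @return Tibble with `pos` (0-based window start) and `mismatches`.
#' @export
find_primer_sites <- function(template, primer, max_mm = 0L) {
  L <- nchar(primer)
  M <- nchar(template)
  empty <- tibble::tibble(pos = integer(), mismatches = integer())
  if (M < L) return(empty)
  p <- iupac_encode(primer, "primer")
  t <- iupac_encode(template, "template")
  concrete <- t %in% c(1L, 2L, 4L, 8L)
  nw <- M - L + 1L
  mm <- integer(nw)
  for (i in seq_len(L)) {
    sl <- i:(nw + i - 1L)
    hit <- concrete[sl] & bitwAnd(t[sl], p[i]) > 0L
    mm <- mm + !hit
  }
  sel <- which(mm <= max_mm)
  tibble::tibble(pos = sel - 1L, mismatches = mm[sel])
}

#' Predict PCR amplicons for a primer pair on a template
#'
#' Scans the template's sense strand for forward-primer sites and for
#' sites of the reverse complement of the reverse primer (reverse primers
#' are given 5'->3' on the antisense strand, the usual convention). Each
#' forward site is paired with the nearest downstream reverse site; the
#' amplicon spans the forward-site start through the reverse-site end.
#' The template's reverse complement is scanned symmetrically and those
#' products are reported in template coordinates with `strand = "-"`.
#' Products longer than `max_len` are dropped.
#'
#' @param template Template sequence.
#' @param fwd,rev Forward and reverse primers (IUPAC, 5'->3'; `rev` on the
#'   antisense strand).
#' @param max_mm Maximum mismatches per primer site (default 0).
#' @param max_len Maximum amplicon length in nt (default 10000, above the
#'   ~4.9 kb of a full-length operon amplicon).
#' @param template_id Optional identifier copied into the result.
#' @return Tibble with `template_id`, `strand`, `start`, `end` (0-based
#'   half-open, template orientation), `length`, `fwd_pos`, `rev_pos`,
#'   `mismatches_fwd`, `mismatches_rev`.
#' @export
predict_amplicons <- function(template, fwd, rev, max_mm = 0L,
                              max_len = 10000L, template_id = NA_character_) {
  scan_sense <- function(tmpl) {
    fsites <- find_primer_sites(tmpl, fwd, max_mm)
    rsites <- find_primer_sites(tmpl, reverse_complement(rev), max_mm)
    lf <- nchar(fwd); lr <- nchar(rev)
    if (nrow(fsites) == 0 || nrow(rsites) == 0) {
      return(tibble::tibble(start = integer(), end = integer(),
                            fwd_pos = integer(), rev_pos = integer(),
                            mismatches_fwd = integer(),
                            mismatches_rev = integer()))
    }
    out <- lapply(seq_len(nrow(fsites)), function(i) {
      f <- fsites$pos[i]
      cand <- which(rsites$pos >= f + lf)    # primer sites must not overlap
      if (length(cand) == 0) return(NULL)
      j <- cand[which.min(rsites$pos[cand])]
      tibble::tibble(
        start = f, end = rsites$pos[j] + lr,
        fwd_pos = f, rev_pos = rsites$pos[j],
        mismatches_fwd = fsites$mismatches[i],
        mismatches_rev = rsites$mismatches[j]
      )
    })
    dplyr::bind_rows(out)
  }
  M <- nchar(template)
  plus <- scan_sense(template)
  if (nrow(plus)) plus$strand <- "+"
  minus <- scan_sense(reverse_complement(template))
  if (nrow(minus)) {
    minus <- dplyr::mutate(minus,
      new_start = M - .data$end,
      new_end = M - .data$start,
      fwd_pos = M - .data$fwd_pos - nchar(fwd),
      rev_pos = M - .data$rev_pos - nchar(rev),
      start = .data$new_start, end = .data$new_end,
      new_start = NULL, new_end = NULL, strand = "-"
    )
  }
  out <- dplyr::bind_rows(plus, minus)
  if (nrow(out) == 0) {
    return(tibble::tibble(template_id = character(), strand = character(),
                          start = integer(), end = integer(),
                          length = integer(), fwd_pos = integer(),
                          rev_pos = integer(), mismatches_fwd = integer(),
                          mismatches_rev = integer()))
  }
  out$length <- out$end - out$start
  out <- out[out$length <= max_len, , drop = FALSE]
  out$template_id <- template_id
  dplyr::arrange(
    dplyr::select(out, "template_id", "strand", "start", "end", "length",
                  "fwd_pos", "rev_pos", "mismatches_fwd", "mismatches_rev"),
    .data$start
  )
}

#' Bundled full-length operon primer pairs
#'
#' The three degenerate primer combinations commonly evaluated for
#' full-length 16S-ITS-23S amplicon generation: 27F paired with 2241R,
#' 27F paired with 2428R (the longest product), and 519F paired with
#' 2428R. Forward primers are 5'->3' on the sense strand, reverse primers
#' 5'->3' on the antisense strand.
#'
#' @return Tibble with columns `name`, `fwd`, `rev`, `source`.
#' @export
rrn_primers <- function() {
  tibble::tibble(
    name = c("16S27F-23S2241R", "16S27F-23S2428R", "16S519F-23S2428R"),
    fwd = c("AGRGTTTGATYHTGGCTCAG", "AGRGTTTGATYHTGGCTCAG",
            "CAGCMGCCGCGGTAA"),
    rev = c("ACCRCCCCAGTHAAACT", "CCRAMCTGTCTCACGACG",
            "CCRAMCTGTCTCACGACG"),
    source = c("published full-operon pair", "novel combination",
               "published full-operon pair")
  )
}

#' Evaluate a primer panel against a sequence database
#'
#' Runs [predict_amplicons()] for every primer pair over every database
#' sequence and reports, per pair: coverage (the percentage of sequences
#' predicted to yield at least one amplicon), the amplicon length
#' distribution, and -- when lineages are supplied -- the phylum
#' composition of the sequences with no predicted amplicon.
#'
#' @param db Tibble of database sequences with columns `id` and
#'   `sequence`; must be non-empty.
#' @param primers Tibble of primer pairs (`name`, `fwd`, `rev`), default
#'   [rrn_primers()].
#' @param lineages Optional tibble (`genome_id`, `lineage`); sequence ids
#'   are parsed as operon ids to recover their source genome.
#' @param max_mm,max_len Passed to [predict_amplicons()].
#' @return An object of class `rrn_pcr_panel`: list with `coverage`
#'   (tibble: `name`, `n_total`, `n_amplified`, `coverage`), `amplicons`
#'   (long tibble of all predictions), `lengths` (five-number summary per
#'   pair) and `misses` (phylum composition of non-amplifying sequences
#'   per pair, `NULL` without lineages). Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
evaluate_primer_panel <- function(db, primers = rrn_primers(),
                                  lineages = NULL, max_mm = 0L,
                                  max_len = 10000L) {
  if (nrow(db) == 0) stop("empty sequence database", call. = FALSE)
  amps <- list()
  cov <- list()
  misses <- list()
  for (i in seq_len(nrow(primers))) {
    pr <- primers[i, ]
    per_seq <- lapply(seq_len(nrow(db)), function(j) {
      predict_amplicons(db$sequence[j], pr$fwd, pr$rev, max_mm = max_mm,
                        max_len = max_len, template_id = db$id[j])
    })
    a <- dplyr::bind_rows(per_seq)
    if (nrow(a)) a$name <- pr$name
    amps[[i]] <- a
    hit <- db$id %in% a$template_id
    cov[[i]] <- tibble::tibble(
      name = pr$name,
      n_total = nrow(db),
      n_amplified = sum(hit),
      coverage = 100 * sum(hit) / nrow(db)
    )
    if (!is.null(lineages) && any(!hit)) {
      gid <- parse_operon_id(db$id[!hit])$genome_id
      lin <- lineages$lineage[match(gid, lineages$genome_id)]
      comp <- phylum_composition(lin[!is.na(lin)])
      comp$name <- pr$name
      misses[[i]] <- comp
    }
  }
  amplicons <- dplyr::bind_rows(amps)
  lengths <- if (nrow(amplicons)) {
    dplyr::summarise(
      dplyr::group_by(amplicons, .data$name),
      n = dplyr::n(),
      min = min(.data$length),
      q1 = unname(stats::quantile(.data$length, 0.25)),
      median = median(.data$length),
      q3 = unname(stats::quantile(.data$length, 0.75)),
      max = max(.data$length),
      .groups = "drop"
    )
  } else {
    tibble::tibble(name = character(), n = integer(), min = numeric(),
                   q1 = numeric(), median = numeric(), q3 = numeric(),
                   max = numeric())
  }
  structure(
    list(coverage = dplyr::bind_rows(cov),
         amplicons = amplicons,
         lengths = lengths,
         misses = if (length(misses)) dplyr::bind_rows(misses) else NULL),
    class = "rrn_pcr_panel"
  )
}

#' @export
print.rrn_pcr_panel <- function(x, ...) {
  cat("In-silico PCR panel over", x$coverage$n_total[1], "sequences\n")
  print(x$coverage)
  invisible(x)
}
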
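# Independent full-matrix dynamic-programming oracle for ends-free global
# alignment, written against the scoring definition only (no banding, no
# shared code with the package implementation).
#
# Model: an alignment is a monotone path of diagonal / up / left moves from
# a free start cell (any cell of row 0 or column 0) to a free end cell (any
# cell of the last row or column). Terminal gaps are outside the path and
# contribute neither score nor columns.

oracle_best_from <- function(a, b, match = 2, mismatch = -3, gap = -5) {
  n <- nchar(a); m <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  # B[i+1, j+1] = best score from cell (i, j) to any stop cell
  B <- matrix(-Inf, n + 1, m + 1)
  B[n + 1, ] <- 0
  B[, m + 1] <- 0
  for (i in n:1) {
    for (j in m:1) {
      s <- if (av[i] == bv[j]) match else mismatch
      B[i, j] <- max(
        s + B[i + 1, j + 1],
        gap + B[i + 1, j],
        gap + B[i, j + 1]
      )
    }
  }
  B
}

oracle_overlap_score <- function(a, b, match = 2, mismatch = -3, gap = -5) {
  B <- oracle_best_from(a, b, match, mismatch, gap)
  starts <- rbind(
    cbind(seq_len(nchar(a) + 1), 1),
    cbind(1, seq_len(nchar(b) + 1))
  )
  max(B[starts])
}

# Set of (matches, columns) pairs achievable by score-optimal alignments.
# Polynomial: per-cell sets are bounded by matches <= min(n, m) and
# columns <= n + m.
oracle_optimal_pairs <- function(a, b, match = 2, mismatch = -3, gap = -5) {
  n <- nchar(a); m <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  B <- oracle_best_from(a, b, match, mismatch, gap)
  memo <- new.env(parent = emptyenv())
  pairs_from <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- NULL
    if ((i == n + 1 || j == m + 1) && B[i, j] == 0) {
      out <- rbind(out, c(0, 0))
    }
    if (i <= n && j <= m) {
      s <- if (av[i] == bv[j]) match else mismatch
      if (s + B[i + 1, j + 1] == B[i, j]) {
        p <- pairs_from(i + 1, j + 1)
        out <- rbind(out, cbind(p[, 1] + (av[i] == bv[j]), p[, 2] + 1))
      }
    }
    if (i <= n && gap + B[i + 1, j] == B[i, j]) {
      p <- pairs_from(i + 1, j)
      out <- rbind(out, cbind(p[, 1], p[, 2] + 1))
    }
    if (j <= m && gap + B[i, j + 1] == B[i, j]) {
      p <- pairs_from(i, j + 1)
      out <- rbind(out, cbind(p[, 1], p[, 2] + 1))
    }
    out <- unique(out)
    memo[[key]] <- out
    out
  }
  opt <- oracle_overlap_score(a, b, match, mismatch, gap)
  res <- NULL
  for (i in seq_len(n + 1)) {
    if (B[i, 1] == opt) res <- rbind(res, pairs_from(i, 1))
  }
  for (j in seq_len(m + 1)) {
    if (B[1, j] == opt) res <- rbind(res, pairs_from(1, j))
  }
  unique(res)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
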
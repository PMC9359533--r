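# Independent oracles and fixture builders used across the suite.
# The suite's fixed seed policy: master seed 101 for every stochastic test.

SUITE_SEED <- 101L

random_dna <- function(len) {
  paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Global alignment score by plain recursion with memoisation -- independent
# of the dynamic-programming implementation under test.
oracle_nw_score <- function(q, r, match = 1, mismatch = -1, gap = -1) {
  qs <- strsplit(q, "")[[1]]
  rs <- strsplit(r, "")[[1]]
  memo <- new.env(hash = TRUE)
  rec <- function(i, j) {
    if (i == 0L) return(j * gap)
    if (j == 0L) return(i * gap)
    k <- paste0(i, ",", j)
    if (!is.null(memo[[k]])) return(memo[[k]])
    v <- max(rec(i - 1L, j - 1L) + (if (qs[i] == rs[j]) match else mismatch),
             rec(i - 1L, j) + gap,
             rec(i, j - 1L) + gap)
    memo[[k]] <- v
    v
  }
  rec(length(qs), length(rs))
}

# Minimal edit distance of an anchor against any substring of a sequence,
# computed column-by-column with the running-minimum trick; an independent
# route to the same quantity as the C++ semi-global scan.
oracle_semiglobal_dist <- function(sequence, anchor) {
  p <- strsplit(anchor, "")[[1]]
  s <- strsplit(sequence, "")[[1]]
  m <- length(p)
  col <- 0:m                      # D[, j = 0]
  best <- col[m + 1L]
  idx <- seq_len(m)
  for (j in seq_along(s)) {
    sub <- col[idx] + (p != s[j])          # diagonal
    del <- col[idx + 1L] + 1L              # from the left (consume seq char)
    tmp <- pmin(sub, del)
    # vertical moves: D[i][j] = min(i, min_{k <= i} tmp[k] + (i - k)),
    # the `i` term entering from the free-start cell D[0][j] = 0
    newcol <- c(0L, pmin(cummin(tmp - idx) + idx, idx))
    col <- newcol
    best <- min(best, col[m + 1L])
  }
  best
}

# Brute-force enumeration over all substrings via utils::adist, including
# the leftmost-start / shortest-span tie-break. Quadratic in the sequence
# length; used on a smaller case count than the DP oracle.
oracle_semiglobal_enum <- function(sequence, anchor) {
  L <- nchar(sequence)
  grid <- expand.grid(start = seq_len(L), end = seq_len(L))
  grid <- grid[grid$end >= grid$start, ]
  subs <- substring(sequence, grid$start, grid$end)
  d <- as.integer(utils::adist(anchor, subs))
  best <- min(d, nchar(anchor))   # empty substring costs nchar(anchor)
  hits <- grid[d == best, , drop = FALSE]
  if (nrow(hits) == 0L) return(list(distance = best, start = NA, end = NA))
  s <- min(hits$start)
  e <- min(hits$end[hits$start == s])
  list(distance = best, start = s, end = e)
}

# Standard-code codon multiplicities, frozen from the textbook table (an
# oracle independent of the Biostrings code table the implementation uses).
CODON_MULTIPLICITY <- c(A = 4, C = 2, D = 2, E = 2, F = 2, G = 4, H = 2,
                        I = 3, K = 2, L = 6, M = 1, N = 2, P = 4, Q = 2,
                        R = 6, S = 6, T = 4, V = 4, W = 1, Y = 2, "*" = 3)

# Small synthetic template with short anchors, for fast structural tests.
toy_template <- function() {
  template_spec(name = "toy",
                upstream_anchor = "ACGTACGTGG",
                downstream_anchor = "CCTTGGAACC",
                left_flank = "TAC",
                right_flank = "TAA",
                template_insert = "ATGGAACATTTTAGATGG",
                designed_random_length = 12L)
}

toy_read <- function(insert, spec = toy_template()) {
  paste0(spec$upstream_anchor, spec$left_flank, insert, spec$right_flank,
         spec$downstream_anchor)
}
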
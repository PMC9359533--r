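AA_SYMBOLS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "*")

#' Theoretical amino-acid frequencies under uniform NNN codons
#'
#' With all four bases equiprobable at each codon position, every one of
#' the 64 codons is equally likely, so each symbol's probability is its
#' codon multiplicity over 64 (e.g. Leu 6/64, Met 1/64, stop 3/64).
#'
#' @return Named numeric vector over the 20 amino acids plus `*`, summing
#'   to 1.
#' @export
theoretical_nnn_frequencies <- function() {
  counts <- table(factor(Biostrings::GENETIC_CODE, levels = AA_SYMBOLS))
  stats::setNames(as.numeric(counts) / 64, AA_SYMBOLS)
}

#' Per-position amino-acid composition of the randomized insert
#'
#' Tallies the residue observed at each insert position (the flank residue
#' and the terminal stop are excluded) across the library, weighted either
#' by read count (default, the read-level average) or uniformly per unique
#' variant, and compares each position with the uniform-NNN expectation
#' via total-variation distance. Sequences shorter than a position are
#' excluded from that position's denominator, so every observed row sums
#' to 1. A chi-square goodness-of-fit statistic per position is included
#' as a secondary, descriptive column (no multiplicity correction).
#'
#' @param variants A `variant_table` from [quantify_variants()].
#' @param weighting `"by_read"` (default) or `"by_variant"`.
#' @return An object of class `composition_table`: list with `observed`
#'   (positions x 21 symbols matrix), `theoretical`, `n` (sequences
#'   contributing per position), `tv_distance` (per position),
#'   `mean_tv_distance`, `chisq` and `chisq_p` (per position).
#' @export
positional_frequencies <- function(variants,
                                   weighting = c("by_read", "by_variant")) {
  weighting <- match.arg(weighting)
  v <- variants$variants
  if (nrow(v) == 0L) stop_("empty variant table")
  core <- sub("\\*$", "", v$peptide)
  insert <- substring(core, 2L)            # drop the flank residue
  w <- if (weighting == "by_read") v$read_count else rep(1L, nrow(v))
  P <- max(nchar(insert))
  if (P == 0L) stop_("no insert residues to tabulate")
  theo <- theoretical_nnn_frequencies()
  obs <- matrix(0, nrow = P, ncol = length(AA_SYMBOLS),
                dimnames = list(position = seq_len(P), symbol = AA_SYMBOLS))
  n <- numeric(P)
  for (p in seq_len(P)) {
    ch <- substr(insert, p, p)
    keep <- nzchar(ch)
    tab <- tapply(w[keep], factor(ch[keep], levels = AA_SYMBOLS), sum)
    tab[is.na(tab)] <- 0
    n[p] <- sum(tab)
    obs[p, ] <- tab / n[p]
  }
  tv <- 0.5 * rowSums(abs(sweep(obs, 2L, theo)))
  chisq <- n * rowSums(sweep(sweep(obs, 2L, theo), 2L, sqrt(theo), "/")^2)
  structure(list(observed = obs, theoretical = theo, n = n,
                 tv_distance = unname(tv),
                 mean_tv_distance = mean(tv),
                 chisq = unname(chisq),
                 chisq_p = stats::pchisq(unname(chisq),
                                         df = length(AA_SYMBOLS) - 1L,
                                         lower.tail = FALSE),
                 weighting = weighting),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat("Positional amino-acid composition (", nrow(x$observed),
      " insert positions, weighting ", x$weighting, ")\n", sep = "")
  cat("  per-position TV distance from uniform-NNN expectation:\n")
  print(round(x$tv_distance, 4))
  cat("  mean:", round(x$mean_tv_distance, 4), "\n")
  invisible(x)
}

#' Flatten a composition table for export
#'
#' @param x A `composition_table`.
#' @return data.frame: one row per insert position with the 21 observed
#'   frequencies, the contributing-sequence count, TV distance and
#'   chi-square columns, followed by one `theoretical` row.
#' @export
composition_as_data_frame <- function(x) {
  stopifnot(inherits(x, "composition_table"))
  df <- data.frame(position = as.character(seq_len(nrow(x$observed))),
                   x$observed, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df$n <- x$n
  df$tv_distance <- x$tv_distance
  df$chisq <- x$chisq
  df$chisq_p <- x$chisq_p
  theo <- data.frame(position = "theoretical",
                     rbind(x$theoretical), check.names = FALSE,
                     stringsAsFactors = FALSE)
  theo$n <- NA_real_
  theo$tv_distance <- NA_real_
  theo$chisq <- NA_real_
  theo$chisq_p <- NA_real_
  rbind(df, theo)
}
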
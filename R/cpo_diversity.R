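#' Round half away from zero
#'
#' The everyday rounding convention (0.5 rounds up in magnitude), as
#' opposed to the IEEE banker's rounding of [round()].
#'
#' @param x Numeric vector.
#' @return Numeric vector of whole numbers.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Fill cumulative probabilities of occurrence (CPO)
#'
#' A variant's CPO is its read fraction multiplied by the observed colony
#' count: an approximate reconstruction of how many transformation-positive
#' colonies carried that variant. By construction the CPO values sum to
#' the colony count. No rounding is applied at this stage.
#'
#' @param variants A `variant_table` from [quantify_variants()].
#' @param colony_count Positive integer: observed transformation-positive
#'   colonies.
#' @return The `variant_table` with the `cpo` column filled and a
#'   `colony_count` element added.
#' @export
compute_cpo <- function(variants, colony_count) {
  stopifnot(inherits(variants, "variant_table"))
  if (length(colony_count) != 1L || is.na(colony_count) || colony_count < 1)
    stop_("colony_count must be a single integer >= 1")
  v <- variants$variants
  if (nrow(v) > 0L && abs(sum(v$fraction) - 1) > 1e-8)
    stop_("variant fractions do not sum to 1")
  v$cpo <- v$fraction * colony_count
  variants$variants <- v
  variants$colony_count <- as.integer(colony_count)
  variants
}

#' Partition variants at CPO = 1
#'
#' Splits the variant repertoire into the group with CPO >= 1 (variants
#' almost certainly present in the library) and the group with CPO < 1
#' (whose CPO values act as presence probabilities), and sums the CPO
#' within each group.
#'
#' @param variants A `variant_table` with `cpo` filled (see
#'   [compute_cpo()]), or a data.frame with a `cpo` column.
#' @return A list with `ge1` and `lt1` (data.frames) and the group sums
#'   `cpo_ge1` and `cpo_lt1`.
#' @export
partition_by_cpo <- function(variants) {
  v <- if (inherits(variants, "variant_table")) variants$variants else variants
  if (anyNA(v$cpo)) stop_("cpo is not filled; run compute_cpo() first")
  ge <- v$cpo >= 1
  list(ge1 = v[ge, , drop = FALSE], lt1 = v[!ge, , drop = FALSE],
       cpo_ge1 = sum(v$cpo[ge]), cpo_lt1 = sum(v$cpo[!ge]))
}

#' Estimate the number of unique variants in the library
#'
#' The library-complexity estimate: the count of variants whose CPO is at
#' least one, plus the cumulative CPO of the remaining variants rounded to
#' the nearest whole number (half away from zero) — the approximate number
#' of colonies occupied by members of the low-CPO group, and hence close
#' to the number of real variants within it.
#'
#' @param n_ge1 Number of variants with CPO >= 1.
#' @param cpo_sum_lt1 Cumulative CPO of the variants with CPO < 1.
#' @return Integer estimate of the number of unique variants.
#' @examples
#' estimate_library_variants(84, 100.70)   # 185
#' @export
estimate_library_variants <- function(n_ge1, cpo_sum_lt1) {
  if (n_ge1 < 0 || cpo_sum_lt1 < 0)
    stop_("inputs must be non-negative")
  as.integer(n_ge1 + round_half_away(cpo_sum_lt1))
}

class_stats <- function(v, colony_count) {
  ge <- v$cpo >= 1
  n_ge1 <- sum(ge)
  cpo_lt1 <- sum(v$cpo[!ge])
  list(
    n_reads = sum(v$read_count),
    reads_cpo_ge1 = sum(v$read_count[ge]),
    reads_cpo_lt1 = sum(v$read_count[!ge]),
    n_variants = nrow(v),
    variants_cpo_ge1 = n_ge1,
    variants_cpo_lt1 = sum(!ge),
    cpo_total = sum(v$cpo),
    cpo_ge1 = sum(v$cpo[ge]),
    cpo_lt1 = cpo_lt1,
    estimated_variants = estimate_library_variants(n_ge1, cpo_lt1),
    cpo_pct_of_colonies = 100 * sum(v$cpo) / colony_count
  )
}

#' Assemble the per-library summary
#'
#' Computes the full library characterization: read tallies, the CPO
#' partition and the complexity estimate, overall and per bias class.
#' Percentages use the denominators established by the summary's internal
#' arithmetic: the passed percentage is over all raw reads, bias-class
#' read percentages are over the passed reads, and per-class estimated
#' variant percentages are the class's total CPO share of the colony
#' count.
#'
#' @param variants A `variant_table` with `cpo` filled.
#' @param colony_count Observed colony count (defaults to the one recorded
#'   by [compute_cpo()]).
#' @param total_reads Number of raw sequencing reads (before extraction).
#' @param mean_read_length Arithmetic mean raw read length in nt.
#' @return An object of class `library_summary`.
#' @seealso [summary_table()] for the tabular rendering.
#' @export
summarize_library <- function(variants, colony_count = variants$colony_count,
                              total_reads = NA_integer_,
                              mean_read_length = NA_real_) {
  stopifnot(inherits(variants, "variant_table"))
  if (is.null(colony_count))
    stop_("colony_count is required (run compute_cpo() or supply it)")
  v <- variants$variants
  if (nrow(v) > 0L && anyNA(v$cpo))
    stop_("cpo is not filled; run compute_cpo() first")
  biased <- v[v$bias_class == "insufficiently_randomized", , drop = FALSE]
  random <- v[v$bias_class == "randomized", , drop = FALSE]
  out <- list(
    colony_count = as.integer(colony_count),
    total_reads = as.integer(total_reads),
    mean_read_length = as.numeric(mean_read_length),
    passed_reads = variants$n_reads,
    passed_pct = 100 * variants$n_reads / total_reads,
    overall = class_stats(v, colony_count),
    insufficiently_randomized = class_stats(biased, colony_count),
    randomized = class_stats(random, colony_count)
  )
  out$insufficiently_randomized$pct_of_passed <-
    100 * out$insufficiently_randomized$n_reads / max(variants$n_reads, 1L)
  out$randomized$pct_of_passed <-
    100 * out$randomized$n_reads / max(variants$n_reads, 1L)
  structure(out, class = "library_summary")
}

#' Format a percentage the way library summaries are reported
#'
#' Two decimal places, except that values that would collapse to 0 or 100
#' keep one significant figure of their distance from the boundary (so
#' 0.00317 prints as 0.003 and 99.99683 as 99.997), and trailing zeros are
#' dropped (75.80 prints as 75.8).
#'
#' @param x Percentage value (0-100 scale).
#' @return Character scalar.
#' @export
format_percent <- function(x) {
  if (is.na(x)) return(NA_character_)
  r <- round(x, 2)
  if (r == 0 && x > 0) r <- signif(x, 1)
  if (r == 100 && x < 100) r <- 100 - signif(100 - x, 1)
  format(r, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
}

#' Tabulate a library summary
#'
#' One row per summary statistic (read tallies, CPO partition sums and
#' complexity estimates, overall and per bias class), with a
#' machine-readable key, the numeric value and a formatted label.
#'
#' @param x A `library_summary`.
#' @return data.frame with columns `key`, `value`, `label`.
#' @export
summary_table <- function(x) {
  stopifnot(inherits(x, "library_summary"))
  rows <- list(
    c("colony_count", x$colony_count, format(x$colony_count)),
    c("total_reads", x$total_reads, format(x$total_reads)),
    c("mean_read_length", x$mean_read_length,
      paste0(format(x$mean_read_length), " bp")),
    c("passed_reads", x$passed_reads,
      sprintf("%d (%s%%)", x$passed_reads, format_percent(x$passed_pct)))
  )
  add_class <- function(prefix, s, pct_passed = NULL) {
    lbl <- function(v) format(round(v, 2), nsmall = 2, trim = TRUE)
    r <- list(
      c(paste0(prefix, "_reads"), s$n_reads,
        if (is.null(pct_passed)) format(s$n_reads) else
          sprintf("%d (%s%%)", s$n_reads, format_percent(pct_passed))),
      c(paste0(prefix, "_reads_cpo_ge1"), s$reads_cpo_ge1,
        format(s$reads_cpo_ge1)),
      c(paste0(prefix, "_reads_cpo_lt1"), s$reads_cpo_lt1,
        format(s$reads_cpo_lt1)),
      c(paste0(prefix, "_unique_variants"), s$n_variants,
        format(s$n_variants)),
      c(paste0(prefix, "_unique_variants_cpo_ge1"), s$variants_cpo_ge1,
        format(s$variants_cpo_ge1)),
      c(paste0(prefix, "_unique_variants_cpo_lt1"), s$variants_cpo_lt1,
        format(s$variants_cpo_lt1)),
      c(paste0(prefix, "_cpo_total"), s$cpo_total, lbl(s$cpo_total)),
      c(paste0(prefix, "_cpo_ge1"), s$cpo_ge1, lbl(s$cpo_ge1)),
      c(paste0(prefix, "_cpo_lt1"), s$cpo_lt1, lbl(s$cpo_lt1)),
      c(paste0(prefix, "_estimated_unique_variants"), s$estimated_variants,
        sprintf("%d (%s%%)", s$estimated_variants,
                format_percent(s$cpo_pct_of_colonies)))
    )
    r
  }
  rows <- c(rows,
            add_class("all", x$overall),
            add_class("insufficiently_randomized",
                      x$insufficiently_randomized,
                      x$insufficiently_randomized$pct_of_passed),
            add_class("randomized", x$randomized, x$randomized$pct_of_passed))
  data.frame(key = vapply(rows, `[`, "", 1L),
             value = as.numeric(vapply(rows, `[`, "", 2L)),
             label = vapply(rows, `[`, "", 3L),
             stringsAsFactors = FALSE)
}

#' @export
print.library_summary <- function(x, ...) {
  tab <- summary_table(x)
  cat("Library summary (colony count ", x$colony_count, ")\n", sep = "")
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-45s %s\n", tab$key[i], tab$label[i]))
  invisible(x)
}
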
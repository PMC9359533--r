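#' Global (Needleman-Wunsch) alignment of two nucleotide strings
#'
#' Maximum-score global alignment under a match/mismatch/linear-gap scoring
#' scheme, with full dynamic programming and a deterministic traceback
#' (ties broken diagonal > up > left, "up" consuming a query character).
#' Because co-optimal alignments can differ in their mismatch/gap split,
#' the reported counts are defined as those of this deterministic
#' traceback.
#'
#' @param query,reference Non-empty A/C/G/T strings.
#' @param params A [classifier_params()] supplying the scores.
#' @return An object of class `nw_alignment`: a list with `aligned_query`,
#'   `aligned_reference` (equal-length strings over `ACGT-`), `score`,
#'   `n_mismatches` (columns where both symbols are bases and differ) and
#'   `n_gap_columns` (columns containing `-` in either row).
#' @examples
#' needleman_wunsch("ACGT", "AGGT")
#' @export
needleman_wunsch <- function(query, reference, params = classifier_params()) {
  if (!nzchar(query) || !nzchar(reference))
    stop_("query and reference must be non-empty")
  if (grepl("[^ACGT]", query) || grepl("[^ACGT]", reference))
    stop_("query and reference must contain only A/C/G/T")
  res <- nw_align_cpp(query, reference, params$match_score,
                      params$mismatch_score, params$gap_score)
  structure(res, class = "nw_alignment")
}

#' @export
print.nw_alignment <- function(x, ...) {
  cat(x$aligned_query, "\n", x$aligned_reference, "\n", sep = "")
  cat("score ", x$score, ", ", x$n_mismatches, " mismatches, ",
      x$n_gap_columns, " gap columns\n", sep = "")
  invisible(x)
}

#' Classify extracted regions as template-biased or randomized
#'
#' Each passed region is globally aligned against the template reference
#' (left flank + template insert + right flank). A region is labelled
#' `insufficiently_randomized` — a template-biased product — when its
#' mismatch count and gap-column count both fall below the classifier
#' bounds (strictly by default); otherwise it is `randomized`. With the
#' designed geometry (60-nt regions vs a 45-nt reference) any global
#' alignment carries at least 15 gap columns, so a full-length random
#' insert can never be labelled template-biased.
#'
#' @param regions Output of [extract_regions()]; every row must have
#'   `passed == TRUE` (filter first).
#' @param spec A [template_spec()].
#' @param params A [classifier_params()].
#' @return The input data.frame with added columns `score`,
#'   `n_mismatches`, `n_gap_columns` and `label`.
#' @export
classify_regions <- function(regions, spec, params = classifier_params()) {
  stopifnot(inherits(spec, "template_spec"))
  if (nrow(regions) == 0L) {
    regions$score <- numeric()
    regions$n_mismatches <- integer()
    regions$n_gap_columns <- integer()
    regions$label <- character()
    return(regions)
  }
  if (!all(regions$passed))
    stop_("classify_regions() requires regions that passed filtering")
  ref <- template_reference(spec)
  counts <- nw_batch_cpp(regions$region, ref, params$match_score,
                         params$mismatch_score, params$gap_score)
  regions$score <- counts[, "score"]
  regions$n_mismatches <- as.integer(counts[, "n_mismatches"])
  regions$n_gap_columns <- as.integer(counts[, "n_gap_columns"])
  biased <- if (params$inclusive_bounds) {
    regions$n_mismatches <= params$max_mismatches &
      regions$n_gap_columns <= params$max_gaps
  } else {
    regions$n_mismatches < params$max_mismatches &
      regions$n_gap_columns < params$max_gaps
  }
  regions$label <- ifelse(biased, "insufficiently_randomized", "randomized")
  regions
}
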
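#' Translate extracted regions to peptides
#'
#' Standard genetic code, frame 0, translating the full region including
#' the flank codons: the output is the last secretion-signal residue, then
#' the insert peptide, then the terminal `*` from the stop-codon flank.
#' Under `keep_symbol` (the default elsewhere in the pipeline) internal
#' stops stay as `*`; under `truncate_at_stop` the peptide is cut after
#' the first `*`.
#'
#' @param regions Character vector of A/C/G/T strings with lengths
#'   divisible by 3.
#' @param internal_stop_policy `"keep_symbol"` or `"truncate_at_stop"`.
#' @return Character vector of peptides over the 20 amino acids plus `*`.
#' @export
translate_regions <- function(regions,
                              internal_stop_policy = c("keep_symbol",
                                                       "truncate_at_stop")) {
  internal_stop_policy <- match.arg(internal_stop_policy)
  if (length(regions) == 0L) return(character())
  if (any(nchar(regions) %% 3L != 0L))
    stop_("region length not divisible by 3")
  if (any(grepl("[^ACGT]", regions)))
    stop_("regions must contain only A/C/G/T")
  pep <- as.character(Biostrings::translate(Biostrings::DNAStringSet(regions)))
  if (internal_stop_policy == "truncate_at_stop")
    pep <- sub("\\*.+$", "*", pep)
  pep
}

#' Collapse classified reads into unique peptide variants
#'
#' Reads are translated and grouped by peptide (synonymous nucleotide
#' reads encoding the same peptide are summed); each variant's fraction is
#' its read count over the total number of classified reads. The bias
#' class of a variant is the majority class of its supporting reads, with
#' ties resolved conservatively to `insufficiently_randomized`.
#'
#' @param classified Output of [classify_regions()].
#' @param internal_stop_policy Passed to [translate_regions()].
#' @param collapse_level `"peptide"` (default) or `"nucleotide"`; the
#'   latter keeps distinct nucleotide regions as separate variants
#'   (diagnostic use) while still reporting their translation.
#' @return A list of class `variant_table` with elements `variants` (a
#'   data.frame: `peptide`, `read_count`, `fraction`, `bias_class`, `cpo`
#'   (NA until [compute_cpo()]), sorted by descending read count then
#'   peptide), `n_reads` (total classified reads R) and `reads_by_class`.
#' @export
quantify_variants <- function(classified,
                              internal_stop_policy = c("keep_symbol",
                                                       "truncate_at_stop"),
                              collapse_level = c("peptide", "nucleotide")) {
  internal_stop_policy <- match.arg(internal_stop_policy)
  collapse_level <- match.arg(collapse_level)
  n_reads <- nrow(classified)
  if (n_reads == 0L) {
    variants <- data.frame(peptide = character(), read_count = integer(),
                           fraction = numeric(), bias_class = character(),
                           cpo = numeric(), stringsAsFactors = FALSE)
    return(structure(list(variants = variants, n_reads = 0L,
                          reads_by_class = c(insufficiently_randomized = 0L,
                                             randomized = 0L)),
                     class = "variant_table"))
  }
  peptide <- translate_regions(classified$region, internal_stop_policy)
  grp <- if (collapse_level == "peptide") peptide else classified$region
  dt <- data.table::data.table(grp = grp, peptide = peptide,
                               label = classified$label)
  v <- dt[, list(peptide = peptide[1L], read_count = .N,
                 n_biased = sum(label == "insufficiently_randomized")),
          by = "grp"]
  v[, "bias_class" := ifelse(v$n_biased * 2L >= v$read_count,
                             "insufficiently_randomized", "randomized")]
  data.table::setorderv(v, c("read_count", "peptide"), order = c(-1L, 1L))
  variants <- data.frame(peptide = v$peptide,
                         read_count = as.integer(v$read_count),
                         fraction = v$read_count / n_reads,
                         bias_class = v$bias_class,
                         cpo = NA_real_, stringsAsFactors = FALSE)
  if (collapse_level == "nucleotide") variants$region <- v$grp
  reads_by_class <- c(
    insufficiently_randomized = sum(classified$label ==
                                      "insufficiently_randomized"),
    randomized = sum(classified$label == "randomized"))
  structure(list(variants = variants, n_reads = n_reads,
                 reads_by_class = reads_by_class),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("Variant table: ", nrow(x$variants), " unique variants from ",
      x$n_reads, " reads\n", sep = "")
  cat("  insufficiently randomized reads:",
      x$reads_by_class[["insufficiently_randomized"]], "\n")
  cat("  randomized reads:             ",
      x$reads_by_class[["randomized"]], "\n")
  print(utils::head(x$variants, 10L))
  invisible(x)
}

#' Peptide length distribution
#'
#' Lengths are computed on the translated string excluding the terminal
#' `*`, so a full designed insert yields last-flank-residue + insert
#' residues (19 for a 54-nt randomized region). Both read counts and
#' unique variant counts are tabulated per length.
#'
#' @param variants A `variant_table` from [quantify_variants()].
#' @return data.frame with columns `length`, `read_count`,
#'   `variant_count`, sorted by length.
#' @export
length_distribution <- function(variants) {
  v <- variants$variants
  len <- nchar(sub("\\*$", "", v$peptide))
  dt <- data.table::data.table(length = len, read_count = v$read_count)
  out <- dt[, list(read_count = sum(read_count), variant_count = .N),
            by = "length"]
  data.table::setorderv(out, "length")
  as.data.frame(out)
}
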
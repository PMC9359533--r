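#' @useDynLib overflapr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

IUPAC_CHARS <- "ACGTRYSWKMBDHVN"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

#' Template specification for a randomized-library amplicon
#'
#' Describes the constant context around the randomized region of the
#' library: the two anchor sequences used to locate the region within a
#' read, the two flanking trinucleotides that are extracted together with
#' the insert (the last codon of the secretion-signal CDS on the left and
#' the stop codon on the right), the template insert CDS that the
#' randomization replaces, and the designed length of the randomized
#' region.
#'
#' @param name Short label for the template (e.g. `"WPA"`).
#' @param upstream_anchor Constant sequence immediately 5' of the extracted
#'   region, exclusive of the left flank trinucleotide. ACGT only.
#' @param downstream_anchor Constant sequence immediately 3' of the
#'   extracted region, exclusive of the right flank trinucleotide.
#' @param left_flank 3-nt string: the last codon of the secretion-signal
#'   CDS.
#' @param right_flank 3-nt string: the stop codon.
#' @param template_insert Template CDS between the flanks; length must be a
#'   multiple of 3.
#' @param designed_random_length Designed length of the randomized region
#'   in nucleotides (a multiple of 3 for in-frame designs).
#' @return An object of class `template_spec`.
#' @seealso [example_template()] for the bundled alpha-factor/alpha-MSH
#'   template.
#' @export
template_spec <- function(name, upstream_anchor, downstream_anchor,
                          left_flank, right_flank, template_insert,
                          designed_random_length) {
  spec <- list(
    name = as.character(name),
    upstream_anchor = toupper(upstream_anchor),
    downstream_anchor = toupper(downstream_anchor),
    left_flank = toupper(left_flank),
    right_flank = toupper(right_flank),
    template_insert = toupper(template_insert),
    designed_random_length = as.integer(designed_random_length)
  )
  class(spec) <- "template_spec"
  validate_template_spec(spec)
  spec
}

validate_template_spec <- function(spec) {
  acgt_only <- function(x) grepl("^[ACGT]+$", x)
  for (fld in c("left_flank", "right_flank")) {
    if (nchar(spec[[fld]]) != 3L || !acgt_only(spec[[fld]]))
      stop_(fld, " must be exactly 3 nt of A/C/G/T, got '", spec[[fld]], "'")
  }
  for (fld in c("upstream_anchor", "downstream_anchor")) {
    if (!nzchar(spec[[fld]]) || !acgt_only(spec[[fld]]))
      stop_(fld, " must be a non-empty A/C/G/T string")
  }
  if (!acgt_only(spec$template_insert) ||
      nchar(spec$template_insert) %% 3L != 0L)
    stop_("template_insert must be A/C/G/T with length divisible by 3")
  if (is.na(spec$designed_random_length) || spec$designed_random_length < 1L)
    stop_("designed_random_length must be a positive integer")
  invisible(spec)
}

#' @export
print.template_spec <- function(x, ...) {
  cat("Template spec '", x$name, "'\n", sep = "")
  cat("  upstream anchor:  ", x$upstream_anchor, "\n", sep = "")
  cat("  left flank:       ", x$left_flank, "\n", sep = "")
  cat("  template insert:  ", x$template_insert,
      " (", nchar(x$template_insert), " nt)\n", sep = "")
  cat("  right flank:      ", x$right_flank, "\n", sep = "")
  cat("  downstream anchor:", x$downstream_anchor, "\n")
  cat("  designed random length:", x$designed_random_length, "nt\n")
  invisible(x)
}

#' Reference sequence a region is classified against
#'
#' The classification reference is the template insert together with its
#' two flanking trinucleotides, i.e. exactly the sequence a template
#' read-through would yield in the extracted region.
#'
#' @param spec A [template_spec()].
#' @return A single nucleotide string.
#' @export
template_reference <- function(spec) {
  paste0(spec$left_flank, spec$template_insert, spec$right_flank)
}

#' Bundled alpha-factor / alpha-MSH template
#'
#' The template used throughout the package's examples and tests: an
#' alpha-factor secretion-signal fusion in which a 39-nt alpha-MSH CDS
#' (13 residues, SYSMEHFRWGKPV) sits between the last codon of the
#' secretion signal (TAC) and the stop codon (TAA), and the designed
#' randomization replaces it with 54 random nucleotides (18 codons).
#'
#' @return A `template_spec`.
#' @export
example_template <- function() {
  template_spec(
    name = "alphaFactor-alphaMSH",
    upstream_anchor = "AGAGAGGCTGAAGCA",
    downstream_anchor = "GCAGCATCT",
    left_flank = "TAC",
    right_flank = "TAA",
    template_insert = "TCTTATTCTATGGAACATTTTAGATGGGGTAAACCAGTT",
    designed_random_length = 54L
  )
}

#' Classifier parameters for template-bias calling
#'
#' A region is called *insufficiently randomized* (template-biased) when
#' its global alignment to the template reference has fewer than
#' `max_mismatches` mismatches and fewer than `max_gaps` gap columns
#' (strict bounds by default; set `inclusive_bounds = TRUE` for `<=`).
#'
#' @param max_mismatches Exclusive upper bound on mismatch columns
#'   (default 10).
#' @param max_gaps Exclusive upper bound on gap columns (default 3). Gaps
#'   are counted per alignment column, not per gap opening.
#' @param match_score,mismatch_score,gap_score Alignment scores (defaults
#'   +1, -1, -1; linear gap penalty).
#' @param inclusive_bounds If `TRUE` the bounds are inclusive (`<=`)
#'   rather than strict (`<`). Default `FALSE`.
#' @return An object of class `classifier_params`.
#' @export
classifier_params <- function(max_mismatches = 10L, max_gaps = 3L,
                              match_score = 1, mismatch_score = -1,
                              gap_score = -1, inclusive_bounds = FALSE) {
  p <- list(
    max_mismatches = as.integer(max_mismatches),
    max_gaps = as.integer(max_gaps),
    match_score = as.numeric(match_score),
    mismatch_score = as.numeric(mismatch_score),
    gap_score = as.numeric(gap_score),
    inclusive_bounds = isTRUE(inclusive_bounds)
  )
  if (p$max_mismatches < 0L || p$max_gaps < 0L)
    stop_("max_mismatches and max_gaps must be >= 0")
  if (!(p$match_score > p$mismatch_score))
    stop_("match_score must exceed mismatch_score")
  class(p) <- "classifier_params"
  p
}

#' Pipeline configuration
#'
#' Bundles the template, the classifier parameters and the extraction
#' options consumed by every pipeline stage.
#'
#' @param template A [template_spec()].
#' @param classifier A [classifier_params()].
#' @param anchor_max_error_rate Maximum error rate for the anchor search: an
#'   anchor match is accepted when its edit distance is at most
#'   `floor(rate * nchar(anchor))`. Must be in `[0, 0.5)`; default 0.1.
#' @param search_both_orientations Also search the reverse complement of
#'   each read (default `TRUE`).
#' @param internal_stop_policy `"keep_symbol"` (default) keeps internal
#'   stops as `*` in translated peptides; `"truncate_at_stop"` cuts the
#'   peptide after the first `*`.
#' @param collapse_level `"peptide"` (default) collapses synonymous reads
#'   to one variant; `"nucleotide"` keeps distinct nucleotide regions
#'   apart (diagnostic use).
#' @param random_seed Integer seed recorded with the run.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(template,
                            classifier = classifier_params(),
                            anchor_max_error_rate = 0.1,
                            search_both_orientations = TRUE,
                            internal_stop_policy = c("keep_symbol",
                                                     "truncate_at_stop"),
                            collapse_level = c("peptide", "nucleotide"),
                            random_seed = 1L) {
  if (!inherits(template, "template_spec"))
    stop_("template must be a template_spec")
  if (!inherits(classifier, "classifier_params"))
    stop_("classifier must be a classifier_params")
  if (!is.numeric(anchor_max_error_rate) ||
      anchor_max_error_rate < 0 || anchor_max_error_rate >= 0.5)
    stop_("anchor_max_error_rate must lie in [0, 0.5)")
  cfg <- list(
    template = template,
    classifier = classifier,
    anchor_max_error_rate = anchor_max_error_rate,
    search_both_orientations = isTRUE(search_both_orientations),
    internal_stop_policy = match.arg(internal_stop_policy),
    collapse_level = match.arg(collapse_level),
    random_seed = as.integer(random_seed)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read amplicon reads from FASTQ or FASTA
#'
#' The format is auto-detected from the first record character (`@` for
#' FASTQ, `>` for FASTA); gzip-compressed files are handled transparently.
#' Sequences are uppercased and `U` is mapped to `T` on ingest. Ambiguous
#' IUPAC bases are retained (regions containing them fail extraction
#' later). Quality strings are carried but never used for filtering.
#'
#' @param path Path to a FASTQ or FASTA file, optionally `.gz`.
#' @return A data.frame with columns `read_id`, `sequence` and `quality`
#'   (`NA` for FASTA input), one row per read in file order.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop_("no such file: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  first <- tryCatch(readLines(con, n = 1L), finally = close(con))
  if (length(first) == 0L || !nzchar(trimws(first[1L]))) {
    return(data.frame(read_id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  }
  lead <- substr(trimws(first[1L]), 1L, 1L)
  fmt <- switch(lead, "@" = "fastq", ">" = "fasta",
                stop_("cannot detect FASTA/FASTQ format of ", path,
                      " (first character '", lead, "')"))
  if (fmt == "fastq") validate_fastq_structure(path)
  x <- tryCatch(
    Biostrings::readBStringSet(path, format = fmt,
                               with.qualities = (fmt == "fastq")),
    error = function(e) stop_("malformed ", toupper(fmt), " file ", path,
                              ": ", conditionMessage(e)))
  seqs <- chartr("U", "T", toupper(as.character(x)))
  qual <- if (fmt == "fastq") {
    as.character(S4Vectors::mcols(x)$qualities)
  } else rep(NA_character_, length(x))
  bad <- which(!nzchar(seqs))
  if (length(bad))
    stop_("empty sequence in record ", bad[1L])
  bad <- which(!grepl(paste0("^[", IUPAC_CHARS, "]+$"), seqs))
  if (length(bad))
    stop_("record ", bad[1L], " contains non-IUPAC characters")
  if (fmt == "fastq") {
    bad <- which(nchar(qual) != nchar(seqs))
    if (length(bad))
      stop_("record ", bad[1L],
            ": sequence and quality strings differ in length")
  }
  data.frame(read_id = names(x), sequence = unname(seqs),
             quality = unname(qual), stringsAsFactors = FALSE)
}

# Structural check of a (4-line-per-record) FASTQ file; the permissive
# stream parser underneath would otherwise accept records whose quality
# string does not match the sequence length.
validate_fastq_structure <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]
  if (length(lines) %% 4L != 0L)
    stop_("malformed FASTQ ", path, ": line count not a multiple of 4")
  n <- length(lines) / 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad))
    stop_("malformed FASTQ record ", bad[1L], " in ", path)
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad))
    stop_("malformed FASTQ record ", bad[1L], " in ", path,
          ": sequence and quality strings differ in length")
  invisible(TRUE)
}

#' Write reads to FASTQ
#'
#' Inverse of [read_fastq()]: records with missing quality are written with
#' a constant `I` quality string.
#'
#' @param reads data.frame with `read_id`, `sequence` and optional
#'   `quality` columns.
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$quality
  if (is.null(qual)) qual <- rep(NA_character_, nrow(reads))
  qual <- ifelse(is.na(qual), strrep("I", nchar(reads$sequence)), qual)
  if (any(nchar(qual) != nchar(reads$sequence)))
    stop_("quality and sequence lengths differ")
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Load a pipeline configuration from a YAML file
#'
#' The file must contain a `template` block with the [template_spec()]
#' fields; `classifier` and `options` blocks are optional and fall back to
#' the documented defaults. See the bundled example at
#' `system.file("extdata", "alpha_msh_template.yaml", package = "overflapr")`.
#'
#' @param path Path to a YAML configuration file.
#' @return A [pipeline_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_("no such config file: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$template)) stop_("config is missing the 'template' block")
  tpl_fields <- c("name", "upstream_anchor", "downstream_anchor",
                  "left_flank", "right_flank", "template_insert",
                  "designed_random_length")
  missing <- setdiff(tpl_fields, names(y$template))
  if (length(missing))
    stop_("config template block is missing: ",
          paste(missing, collapse = ", "))
  template <- do.call(template_spec, y$template[tpl_fields])
  cl <- y$classifier %||% list()
  classifier <- classifier_params(
    max_mismatches = cl$max_mismatches %||% 10L,
    max_gaps = cl$max_gaps %||% 3L,
    match_score = cl$match_score %||% 1,
    mismatch_score = cl$mismatch_score %||% -1,
    gap_score = cl$gap_score %||% -1,
    inclusive_bounds = cl$inclusive_bounds %||% FALSE
  )
  op <- y$options %||% list()
  pipeline_config(
    template = template,
    classifier = classifier,
    anchor_max_error_rate = op$anchor_max_error_rate %||% 0.1,
    search_both_orientations = op$search_both_orientations %||% TRUE,
    internal_stop_policy = op$internal_stop_policy %||% "keep_symbol",
    collapse_level = op$collapse_level %||% "peptide",
    random_seed = op$random_seed %||% 1L
  )
}

#' Write a pipeline configuration to YAML
#'
#' @param config A [pipeline_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  y <- list(
    template = unclass(config$template),
    classifier = unclass(config$classifier),
    options = list(
      anchor_max_error_rate = config$anchor_max_error_rate,
      search_both_orientations = config$search_both_orientations,
      internal_stop_policy = config$internal_stop_policy,
      collapse_level = config$collapse_level,
      random_seed = config$random_seed
    )
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Reverse complement of nucleotide strings
#'
#' @param x Character vector of IUPAC nucleotide strings.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
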
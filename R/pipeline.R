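SCHEMA_VERSION <- "1.0"

#' Run the full analysis on an in-memory read set
#'
#' Extraction, template-bias classification, peptide-level variant
#' quantification, CPO computation, the library summary, the peptide
#' length distribution and the positional composition, in one call.
#'
#' @param reads data.frame as returned by [read_fastq()] or
#'   [generate_reads()].
#' @param config A [pipeline_config()].
#' @param colony_count Observed transformation-positive colony count.
#' @return A list of class `library_analysis` with elements `regions`,
#'   `classified`, `variants` (a `variant_table` with CPO filled),
#'   `summary` (a `library_summary`), `lengths`, `composition` (`NULL`
#'   when no reads passed) and `tally`.
#' @export
analyze_reads <- function(reads, config, colony_count) {
  stopifnot(inherits(config, "pipeline_config"))
  regions <- extract_regions(reads, config)
  passed <- regions[regions$passed, , drop = FALSE]
  classified <- classify_regions(passed, config$template, config$classifier)
  variants <- quantify_variants(classified,
                                internal_stop_policy =
                                  config$internal_stop_policy,
                                collapse_level = config$collapse_level)
  if (variants$n_reads > 0L) {
    variants <- compute_cpo(variants, colony_count)
    composition <- positional_frequencies(variants)
  } else {
    warning("no reads passed extraction filters; summary is empty",
            call. = FALSE)
    variants$colony_count <- as.integer(colony_count)
    composition <- NULL
  }
  summary <- summarize_library(
    variants, colony_count = colony_count,
    total_reads = nrow(reads),
    mean_read_length = if (nrow(reads)) mean(nchar(reads$sequence)) else
      NA_real_)
  structure(list(regions = regions, classified = classified,
                 variants = variants, summary = summary,
                 lengths = length_distribution(variants),
                 composition = composition,
                 tally = extraction_tally(regions)),
            class = "library_analysis")
}

#' @export
print.library_analysis <- function(x, ...) {
  cat("Library analysis:", x$tally[["total"]], "reads,",
      x$tally[["passed"]], "passed extraction\n")
  print(x$summary)
  invisible(x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

config_digest <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(out_dir, config, seed, inputs, tallies) {
  manifest <- list(
    schema_version = SCHEMA_VERSION,
    tool = "overflapr",
    tool_version = as.character(utils::packageVersion("overflapr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_digest = config_digest(config),
    config = yaml::yaml.load(yaml::as.yaml(list(
      template = unclass(config$template),
      classifier = unclass(config$classifier)))),
    input_digests = as.list(tools::md5sum(inputs)),
    tallies = as.list(tallies)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Analyze FASTQ file(s) and write the report files
#'
#' Multiple FASTQ inputs are treated as one library (concatenated). Writes
#' `variants.tsv`, `summary.tsv`, `summary.json`, `lengths.tsv`,
#' `composition.tsv`, an optional per-read `regions.tsv` audit log, and a
#' `manifest.json` recording the configuration digest, input digests and
#' per-stage read tallies. A run in which no read passes the filters
#' completes with a warning and an empty summary.
#'
#' @param fastq Character vector of FASTQ/FASTA paths.
#' @param config A [pipeline_config()] or the path of a YAML config file.
#' @param colony_count Observed colony count (mandatory: the pipeline has
#'   no way to infer it from reads).
#' @param out_dir Output directory, created if needed.
#' @param write_regions Also write the per-read audit log (default
#'   `FALSE`).
#' @return The `library_analysis`, invisibly.
#' @export
run_analyze <- function(fastq, config, colony_count, out_dir,
                        write_regions = FALSE) {
  if (is.character(config)) config <- load_config(config)
  reads <- do.call(rbind, lapply(fastq, read_fastq))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- analyze_reads(reads, config, colony_count)
  write_tsv(res$variants$variants, file.path(out_dir, "variants.tsv"))
  tab <- summary_table(res$summary)
  write_tsv(tab, file.path(out_dir, "summary.tsv"))
  jsonlite::write_json(
    c(list(schema_version = SCHEMA_VERSION,
           config_digest = config_digest(config)),
      stats::setNames(as.list(tab$value), tab$key)),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  write_tsv(res$lengths, file.path(out_dir, "lengths.tsv"))
  if (!is.null(res$composition))
    write_tsv(composition_as_data_frame(res$composition),
              file.path(out_dir, "composition.tsv"))
  if (write_regions)
    write_tsv(res$regions, file.path(out_dir, "regions.tsv"))
  write_manifest(out_dir, config, config$random_seed, fastq, res$tally)
  invisible(res)
}

#' Simulate a library and write reads, truth and model description
#'
#' Writes `reads.fastq`, `truth.tsv`, `model.json` and `manifest.json`
#' into `out_dir`. The same seed always produces byte-identical truth and
#' reads.
#'
#' @param out_dir Output directory, created if needed.
#' @param model A [library_model()] or a preset name for
#'   [library_preset()].
#' @param config A [pipeline_config()] supplying the template (defaults
#'   to the bundled alpha-factor/alpha-MSH template).
#' @param error_model An [error_model()].
#' @param n_reads Number of reads to simulate.
#' @param seed Master seed; all stage substreams derive from it.
#' @return A list with `reads`, `truth` and the file paths, invisibly.
#' @export
run_simulate <- function(out_dir, model = "wpa",
                         config = pipeline_config(example_template()),
                         error_model = overflapr::error_model(),
                         n_reads = 10000L, seed = 1L) {
  if (is.character(model)) model <- library_preset(model)
  stopifnot(inherits(model, "library_model"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- generate_truth(model, config$template, seed = seed)
  reads <- generate_reads(truth, config$template, error_model,
                          n_reads = n_reads, seed = seed)
  fq <- file.path(out_dir, "reads.fastq")
  write_fastq(reads, fq)
  tt <- file.path(out_dir, "truth.tsv")
  write_tsv(truth, tt)
  jsonlite::write_json(
    list(schema_version = SCHEMA_VERSION, seed = seed, n_reads = n_reads,
         model = unclass(model), error_model = unclass(error_model),
         template = unclass(config$template)),
    file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, config, seed, fq,
                 c(n_variants = nrow(truth), n_reads = n_reads))
  invisible(list(reads = reads, truth = truth, fastq = fq, truth_path = tt))
}
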
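test_that("truth generation honors the model contracts and is seed-reproducible", {
  spec <- example_template()
  # degenerate settings: uniform abundance, no bias, no aberrations
  m <- library_model(n_true_variants = 100L, colony_count = 100L)
  t1 <- generate_truth(m, spec, seed = SUITE_SEED)
  expect_equal(nrow(t1), 100L)
  expect_true(all(t1$origin == "random"))
  expect_true(all(nchar(t1$insert) == 54L))
  expect_equal(t1$abundance, rep(1 / 100, 100))
  expect_equal(sum(t1$abundance), 1, tolerance = 1e-12)
  expect_identical(generate_truth(m, spec, seed = SUITE_SEED), t1)
  expect_false(identical(generate_truth(m, spec, seed = SUITE_SEED + 1L), t1))

  # template-like mass sums exactly to the bias fraction
  mb <- library_model(n_true_variants = 50L, n_template_variants = 8L,
                      template_bias_fraction = 0.5, abundance_skew = 2,
                      colony_count = 100L)
  tb <- generate_truth(mb, spec, seed = SUITE_SEED)
  expect_equal(sum(tb$abundance[tb$origin == "template_like"]), 0.5,
               tolerance = 1e-12)
  expect_equal(sum(tb$abundance), 1, tolerance = 1e-12)

  expect_error(library_model(n_template_variants = 0L,
                             template_bias_fraction = 0.5),
               "n_template_variants")
})

test_that("read generation assembles anchored reads with both orientations", {
  spec <- example_template()
  m <- library_model(n_true_variants = 20L, colony_count = 20L)
  truth <- generate_truth(m, spec, seed = SUITE_SEED)
  noerr <- error_model(substitution_rate = 0, homopolymer_indel_rate = 0)
  reads <- generate_reads(truth, spec, noerr, n_reads = 500L,
                          seed = SUITE_SEED)
  expect_equal(nrow(reads), 500L)
  expect_identical(generate_reads(truth, spec, noerr, 500L, SUITE_SEED),
                   reads)
  # about half the reads reverse-complemented
  expect_gt(mean(reads$true_orientation == "reverse_complement"), 0.4)
  expect_lt(mean(reads$true_orientation == "reverse_complement"), 0.6)
  fwd <- ifelse(reads$true_orientation == "forward", reads$sequence,
                reverse_complement(reads$sequence))
  expect_true(all(startsWith(fwd, spec$upstream_anchor)))
  expect_true(all(endsWith(fwd, spec$downstream_anchor)))
  expect_error(generate_reads(truth, spec, noerr, 0L), "n_reads")
})

test_that("a noiseless unbiased library round-trips through the pipeline exactly", {
  spec <- example_template()
  cfg <- pipeline_config(spec)
  m <- library_model(n_true_variants = 50L, colony_count = 50L)
  truth <- generate_truth(m, spec, seed = SUITE_SEED)
  noerr <- error_model(0, 0)
  reads <- generate_reads(truth, spec, noerr, n_reads = 3000L,
                          seed = SUITE_SEED)
  res <- analyze_reads(reads, cfg, colony_count = m$colony_count)
  # every read passes and is classified randomized
  expect_equal(unname(res$tally[["passed"]]), 3000L)
  expect_true(all(res$classified$label == "randomized"))
  # the recovered variant set is exactly the truth's peptide set
  truth_pep <- translate_regions(paste0(spec$left_flank, truth$insert,
                                        spec$right_flank))
  expect_setequal(res$variants$variants$peptide, unique(truth_pep))
  # read counts are multinomially consistent with uniform truth abundances
  counts <- res$variants$variants$read_count
  chi <- sum((counts - 60)^2 / 60)   # 3000 reads over 50 equal variants
  expect_gt(stats::pchisq(chi, df = 49, lower.tail = FALSE), 1e-4)
})

test_that("substitution and homopolymer error processes hit at the configured rates", {
  withr::local_seed(SUITE_SEED)
  spec <- example_template()
  m <- library_model(n_true_variants = 5L, colony_count = 5L)
  truth <- generate_truth(m, spec, seed = SUITE_SEED)
  clean <- generate_reads(truth, spec, error_model(0, 0), 2000L, SUITE_SEED)
  subs <- generate_reads(truth, spec, error_model(0.01, 0), 2000L, SUITE_SEED)
  # same sampling substream: sequences pair up, lengths unchanged by subs
  expect_equal(nchar(subs$sequence), nchar(clean$sequence))
  diffs <- mapply(function(a, b) sum(utf8ToInt(a) != utf8ToInt(b)),
                  clean$sequence, subs$sequence)
  total <- sum(nchar(clean$sequence))
  expect_gt(sum(diffs) / total, 0.005)
  expect_lt(sum(diffs) / total, 0.015)

  indel <- generate_reads(truth, spec, error_model(0, 0.5), 2000L, SUITE_SEED)
  dl <- nchar(indel$sequence) - nchar(clean$sequence)
  expect_true(any(dl != 0))
  # single-base events per homopolymer run: length changes stay small
  expect_true(all(abs(dl) <= 10))
})

test_that("presets encode the three library archetypes", {
  wpa <- library_preset("wpa")
  expect_equal(wpa$template_bias_fraction, 0.5)
  expect_equal(wpa$colony_count, 3802L)
  ofl <- library_preset("overflap")
  expect_equal(ofl$n_template_variants, 1L)
  asym <- library_preset("overflap-asym")
  expect_equal(asym$template_bias_fraction, 0)
  expect_equal(asym$colony_count, 4865L)
  expect_error(library_preset("nope"))
})
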
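mk_variant_table <- function(read_counts,
                             bias = rep("randomized", length(read_counts))) {
  n <- sum(read_counts)
  variants <- data.frame(
    peptide = sprintf("PEP%03d*", seq_along(read_counts)),
    read_count = as.integer(read_counts),
    fraction = read_counts / n,
    bias_class = bias,
    cpo = NA_real_, stringsAsFactors = FALSE)
  structure(list(variants = variants, n_reads = n,
                 reads_by_class = c(
                   insufficiently_randomized =
                     sum(read_counts[bias == "insufficiently_randomized"]),
                   randomized = sum(read_counts[bias == "randomized"]))),
            class = "variant_table")
}

test_that("CPO is fraction times colony count and sums to the colony count", {
  vt <- compute_cpo(mk_variant_table(10L), 3802L)
  expect_equal(vt$variants$cpo, 3802)

  vt <- compute_cpo(mk_variant_table(c(5L, 5L)), 10L)
  expect_equal(vt$variants$cpo, c(5, 5))

  withr::local_seed(SUITE_SEED)
  vt <- compute_cpo(mk_variant_table(sample(1:500, 60)), 4865L)
  expect_equal(sum(vt$variants$cpo), 4865, tolerance = 1e-12)
  expect_error(compute_cpo(mk_variant_table(10L), 0), "colony_count")
})

test_that("the CPO partition splits inclusively at one", {
  vt <- mk_variant_table(c(20L, 3L, 10L, 7L))   # fractions /40
  vt <- compute_cpo(vt, 4L)                     # cpos 2.0, 0.3, 1.0, 0.7
  part <- partition_by_cpo(vt)
  expect_equal(part$ge1$cpo, c(2, 1))
  expect_equal(part$lt1$cpo, c(0.3, 0.7))
  expect_equal(part$cpo_ge1, 3)
  expect_equal(part$cpo_lt1, 1)

  # degenerate: everything below one
  vt <- compute_cpo(mk_variant_table(rep(1L, 10)), 5L)
  part <- partition_by_cpo(vt)
  expect_equal(nrow(part$ge1), 0L)
  expect_equal(part$cpo_lt1, 5)
  expect_error(partition_by_cpo(mk_variant_table(3L)), "compute_cpo")
})

test_that("the library-size estimator reproduces the published worked examples", {
  expect_identical(estimate_library_variants(84, 100.70), 185L)
  expect_identical(estimate_library_variants(464, 326.75), 791L)
  expect_identical(estimate_library_variants(627, 4039.58), 4667L)
  expect_identical(estimate_library_variants(0, 0), 0L)
  expect_error(estimate_library_variants(-1, 0), "non-negative")
})

test_that("rounding is half away from zero and the estimator is monotone", {
  expect_equal(round_half_away(c(0.5, 1.5, 2.5, -0.5)), c(1, 2, 3, -1))
  withr::local_seed(SUITE_SEED)
  n <- sort(sample(0:500, 30))
  s <- sort(runif(30, 0, 400))
  est_n <- vapply(n, estimate_library_variants, 1L, cpo_sum_lt1 = 50)
  est_s <- vapply(s, function(x) estimate_library_variants(10, x), 1L)
  expect_true(all(diff(est_n) >= 0))
  expect_true(all(diff(est_s) >= 0))
})

test_that("summarize_library assembles consistent per-class tallies", {
  vt <- mk_variant_table(c(40L, 25L, 20L, 10L, 3L, 2L),
                         bias = c("insufficiently_randomized", "randomized",
                                  "insufficiently_randomized", "randomized",
                                  "randomized", "insufficiently_randomized"))
  vt <- compute_cpo(vt, 20L)
  s <- summarize_library(vt, total_reads = 200L, mean_read_length = 84)
  expect_equal(s$passed_reads, 100L)
  expect_equal(s$passed_pct, 50)
  # per-class quantities sum to the overall ones
  for (fld in c("n_reads", "n_variants", "cpo_total", "cpo_ge1", "cpo_lt1",
                "variants_cpo_ge1", "reads_cpo_ge1")) {
    expect_equal(s$insufficiently_randomized[[fld]] + s$randomized[[fld]],
                 s$overall[[fld]], info = fld)
  }
  expect_equal(s$overall$cpo_total, 20, tolerance = 1e-12)
  # the estimate can exceed the colony count by at most one
  expect_lte(s$overall$estimated_variants, s$colony_count + 1L)
  tab <- summary_table(s)
  expect_true(!anyNA(tab$value))
  expect_equal(tab$value[tab$key == "all_cpo_total"], 20)
})

test_that("percent formatting matches conventional reporting precision", {
  expect_equal(format_percent(100 * 62636 / 140960), "44.44")
  expect_equal(format_percent(100 * 94609 / 139461), "67.84")
  expect_equal(format_percent(100 * 611478 / 806671), "75.8")
  expect_equal(format_percent(100 * 31447 / 62636), "50.21")
  expect_equal(format_percent(100 * 3 / 94609), "0.003")
  expect_equal(format_percent(100 * 94606 / 94609), "99.997")
  expect_equal(format_percent(0), "0")
  expect_equal(format_percent(100), "100")
})
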
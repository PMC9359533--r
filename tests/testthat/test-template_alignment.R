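test_that("needleman_wunsch reproduces the small worked alignments", {
  id <- needleman_wunsch("ACGT", "ACGT")
  expect_equal(id$score, 4)
  expect_equal(id$n_mismatches, 0L)
  expect_equal(id$n_gap_columns, 0L)

  sub <- needleman_wunsch("ACGT", "AGGT")
  expect_equal(sub$score, 2)          # 3 matches - 1 mismatch
  expect_equal(sub$n_mismatches, 1L)
  expect_equal(sub$n_gap_columns, 0L)

  del <- needleman_wunsch("ACGT", "ACT")
  expect_equal(del$score, 2)          # 3 matches - 1 gap column
  expect_equal(del$n_mismatches, 0L)
  expect_equal(del$n_gap_columns, 1L)

  expect_error(needleman_wunsch("", "ACGT"), "non-empty")
})

test_that("alignment output is a consistent trace of its inputs", {
  withr::local_seed(SUITE_SEED)
  for (i in 1:100) {
    q <- random_dna(sample(1:20, 1))
    r <- random_dna(sample(1:20, 1))
    al <- needleman_wunsch(q, r)
    expect_equal(nchar(al$aligned_query), nchar(al$aligned_reference))
    expect_equal(gsub("-", "", al$aligned_query), q)
    expect_equal(gsub("-", "", al$aligned_reference), r)
    # column accounting: matches + mismatches + gap columns = length
    qs <- strsplit(al$aligned_query, "")[[1]]
    rs <- strsplit(al$aligned_reference, "")[[1]]
    gap <- qs == "-" | rs == "-"
    expect_equal(sum(gap), al$n_gap_columns)
    expect_equal(sum(!gap & qs != rs), al$n_mismatches)
    # score recomputes from the trace
    expect_equal(sum(!gap & qs == rs) - al$n_mismatches - al$n_gap_columns,
                 al$score)
    # gap columns bounded below by the length difference
    expect_gte(al$n_gap_columns, abs(nchar(q) - nchar(r)))
  }
})

test_that("scores match the independent recursive oracle on random pairs", {
  withr::local_seed(SUITE_SEED)
  for (i in 1:120) {
    q <- random_dna(sample(1:12, 1))
    r <- random_dna(sample(1:12, 1))
    expect_equal(needleman_wunsch(q, r)$score, oracle_nw_score(q, r),
                 info = paste(q, r))
  }
})

test_that("classification separates template-like from randomized regions", {
  spec <- example_template()
  ref <- template_reference(spec)
  params <- classifier_params()
  regions <- function(x) data.frame(read_id = seq_along(x),
                                    orientation = "forward", region = x,
                                    passed = TRUE,
                                    fail_reason = NA_character_,
                                    stringsAsFactors = FALSE)
  # template read-through: 0 mismatches, 0 gaps
  out <- classify_regions(regions(ref), spec, params)
  expect_equal(out$n_mismatches, 0L)
  expect_equal(out$label, "insufficiently_randomized")

  # designed-length random inserts can never look template-like:
  # |60 - 45| = 15 gap columns >= the gap bound
  withr::local_seed(SUITE_SEED)
  rnd <- vapply(1:50, function(i)
    paste0("TAC", random_dna(54), "TAA"), "")
  out <- classify_regions(regions(rnd), spec, params)
  expect_true(all(out$n_gap_columns >= 15L))
  expect_true(all(out$label == "randomized"))
})

test_that("the mismatch/gap bounds are strict and verified on constructed mutants", {
  spec <- example_template()
  ref <- template_reference(spec)
  params <- classifier_params()
  mk_regions <- function(x) data.frame(read_id = seq_along(x),
                                       orientation = "forward", region = x,
                                       passed = TRUE,
                                       fail_reason = NA_character_,
                                       stringsAsFactors = FALSE)
  substitute_at <- function(seq, pos) {
    ch <- strsplit(seq, "")[[1]]
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste0(ch, collapse = "")
  }
  withr::local_seed(SUITE_SEED)
  # 9 substitutions + 2 single-base deletions -> still below both bounds
  nine <- substitute_at(ref, sample(nchar(ref), 9))
  nine_two_gaps <- paste0(substr(nine, 1, 10), substr(nine, 12, 30),
                          substring(nine, 32))
  out <- classify_regions(mk_regions(nine_two_gaps), spec, params)
  expect_lte(out$n_mismatches, 9L)
  expect_lte(out$n_gap_columns, 2L)
  expect_equal(out$label, "insufficiently_randomized")

  # 10 substitutions -> at the mismatch bound -> randomized
  ten <- substitute_at(ref, seq(1, 28, by = 3))
  out <- classify_regions(mk_regions(ten), spec, params)
  expect_equal(out$n_mismatches, 10L)
  expect_equal(out$label, "randomized")

  # inclusive bounds flip exactly that call
  out <- classify_regions(mk_regions(ten), spec,
                          classifier_params(inclusive_bounds = TRUE))
  expect_equal(out$label, "insufficiently_randomized")

  expect_error(classify_regions(
    data.frame(read_id = 1, orientation = "forward", region = ref,
               passed = FALSE, fail_reason = "flank_mismatch"),
    spec, params), "passed")
})
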
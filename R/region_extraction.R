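#' Find the best approximate occurrence of an anchor within a sequence
#'
#' Semi-global (cutadapt-like) search: the whole anchor is aligned against
#' a substring of `sequence` under unit-cost edits (substitutions and
#' indels). The lowest-edit-distance occurrence wins; ties are broken by
#' leftmost start, then shortest span. A match is accepted only when its
#' edit distance is at most `floor(max_error_rate * nchar(anchor))`;
#' partial anchor occurrences hanging over the sequence ends are never
#' reported.
#'
#' @param sequence Nucleotide string to search in.
#' @param anchor Non-empty anchor string.
#' @param max_error_rate Error tolerance in `[0, 0.5)`.
#' @return A list with `start`, `end` (1-based, inclusive) and `distance`,
#'   or `NULL` when no acceptable occurrence exists.
#' @export
find_anchor <- function(sequence, anchor, max_error_rate = 0.1) {
  if (!nzchar(anchor)) stop_("anchor must be non-empty")
  if (max_error_rate < 0 || max_error_rate >= 0.5)
    stop_("max_error_rate must lie in [0, 0.5)")
  hit <- anchor_scan_cpp(toupper(sequence), toupper(anchor))
  kmax <- floor(max_error_rate * nchar(anchor))
  if (hit[["distance"]] > kmax) return(NULL)
  list(start = hit[["start"]], end = hit[["end"]],
       distance = hit[["distance"]])
}

FAIL_REASONS <- c("no_upstream_anchor", "no_downstream_anchor",
                  "flank_mismatch", "length_not_multiple_of_3",
                  "ambiguous_base", "empty_region")

# Scan one orientation of a read set: upstream anchor first, then the
# downstream anchor restricted to the suffix after the upstream match (which
# enforces anchor order). Returns per-read region and total anchor distance,
# NA when either anchor is absent.
scan_orientation <- function(seqs, spec, rate) {
  n <- length(seqs)
  up_k <- floor(rate * nchar(spec$upstream_anchor))
  dn_k <- floor(rate * nchar(spec$downstream_anchor))
  up <- anchor_scan_batch_cpp(seqs, spec$upstream_anchor)
  up_ok <- up[, "distance"] <= up_k
  region <- rep(NA_character_, n)
  total <- rep(NA_integer_, n)
  dn_found <- rep(FALSE, n)
  if (any(up_ok)) {
    idx <- which(up_ok)
    suffix <- substring(seqs[idx], up[idx, "end"] + 1L)
    dn <- anchor_scan_batch_cpp(suffix, spec$downstream_anchor)
    ok <- dn[, "distance"] <= dn_k
    dn_found[idx] <- ok
    hit <- idx[ok]
    region[hit] <- substr(suffix[ok], 1L, dn[ok, "start"] - 1L)
    total[hit] <- up[hit, "distance"] + dn[ok, "distance"]
  }
  list(up_found = up_ok, found = dn_found, region = region, total = total)
}

#' Extract the randomized region (plus flanks) from reads
#'
#' Locates the upstream and downstream anchors in each read (and, when
#' configured, in its reverse complement), extracts the sequence strictly
#' between the two anchor matches — i.e. left flank + insert + right flank
#' — and applies the structural retention filters in fixed order:
#' empty region, ambiguous base, flank mismatch (the first and last
#' trinucleotides must equal the template flanks exactly), length not a
#' multiple of three. When both orientations yield anchors, the one with
#' the smaller total anchor edit distance wins (ties go to forward).
#'
#' @param reads data.frame as returned by [read_fastq()].
#' @param config A [pipeline_config()].
#' @return data.frame with one row per read: `read_id`, `orientation`
#'   (`"forward"`, `"reverse_complement"` or `NA` when no anchors were
#'   found), `region`, `passed` and `fail_reason` (`NA` when passed).
#' @export
extract_regions <- function(reads, config) {
  stopifnot(inherits(config, "pipeline_config"))
  spec <- config$template
  rate <- config$anchor_max_error_rate
  n <- nrow(reads)
  if (n == 0L) {
    return(data.frame(read_id = character(), orientation = character(),
                      region = character(), passed = logical(),
                      fail_reason = character(), stringsAsFactors = FALSE))
  }
  seqs <- toupper(reads$sequence)
  fwd <- scan_orientation(seqs, spec, rate)
  if (config$search_both_orientations) {
    rev <- scan_orientation(reverse_complement(seqs), spec, rate)
  } else {
    rev <- list(up_found = rep(FALSE, n), found = rep(FALSE, n),
                region = rep(NA_character_, n), total = rep(NA_integer_, n))
  }

  use_rev <- rev$found & (!fwd$found | (rev$total < ifelse(is.na(fwd$total),
                                                           .Machine$integer.max,
                                                           fwd$total)))
  orientation <- ifelse(use_rev, "reverse_complement",
                        ifelse(fwd$found, "forward", NA_character_))
  region <- ifelse(use_rev, rev$region, fwd$region)
  found <- fwd$found | rev$found

  fail <- rep(NA_character_, n)
  no_up <- !found & !(fwd$up_found | rev$up_found)
  fail[!found] <- "no_downstream_anchor"
  fail[no_up] <- "no_upstream_anchor"

  idx <- which(found)
  if (length(idx)) {
    r <- region[idx]
    len <- nchar(r)
    reason <- rep(NA_character_, length(idx))
    reason[len == 0L] <- "empty_region"
    chk <- is.na(reason) & grepl("[^ACGT]", r)
    reason[chk] <- "ambiguous_base"
    chk <- is.na(reason) &
      (substr(r, 1L, 3L) != spec$left_flank |
         substr(r, len - 2L, len) != spec$right_flank)
    reason[chk] <- "flank_mismatch"
    chk <- is.na(reason) & (len %% 3L != 0L)
    reason[chk] <- "length_not_multiple_of_3"
    fail[idx] <- reason
  }

  data.frame(read_id = reads$read_id, orientation = orientation,
             region = region, passed = is.na(fail), fail_reason = fail,
             stringsAsFactors = FALSE)
}

#' Tally extraction outcomes
#'
#' @param regions Output of [extract_regions()].
#' @return Named integer vector: total, passed, and one entry per failure
#'   reason (tallies reconcile: total = passed + sum of failures).
#' @export
extraction_tally <- function(regions) {
  fails <- table(factor(regions$fail_reason, levels = FAIL_REASONS))
  c(total = nrow(regions), passed = sum(regions$passed),
    as.integer(fails))  |>
    stats::setNames(c("total", "passed", FAIL_REASONS))
}
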
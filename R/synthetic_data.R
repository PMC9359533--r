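#' Statistical model of a randomized plasmid library
#'
#' Describes the true variant pool a simulated library is drawn from: a
#' mixture of template-like inserts (the template CDS with sparse
#' substitutions, emulating template-biased amplification products) and
#' fully random inserts of the designed length, with heavy-tailed
#' ("jackpot") per-variant abundances and occasional insert-length
#' aberrations.
#'
#' @param n_true_variants Total number of distinct variants in the pool.
#' @param n_template_variants How many of them are template-like.
#' @param template_bias_fraction Fraction of the total read mass carried
#'   by the template-like pool (0.5 emulates a heavily biased library).
#' @param template_mutation_rate Per-base substitution rate applied to
#'   template-like inserts (default 0.02).
#' @param abundance_skew Log-normal sigma of the per-variant abundances;
#'   0 gives a uniform library, ~2.5 reproduces a handful of variants
#'   holding most of the reads.
#' @param indel_aberration_rate Probability that a random insert carries a
#'   length change; whole-codon changes with probability 0.8, otherwise
#'   frame-breaking (default 0).
#' @param colony_count Colony count reported alongside the simulated
#'   reads; deliberately decoupled from `n_true_variants` so the
#'   complexity estimator can be probed under miscounted colonies.
#' @return An object of class `library_model`.
#' @export
library_model <- function(n_true_variants = 1000L,
                          n_template_variants = 0L,
                          template_bias_fraction = 0,
                          template_mutation_rate = 0.02,
                          abundance_skew = 0,
                          indel_aberration_rate = 0,
                          colony_count = 4000L) {
  m <- list(n_true_variants = as.integer(n_true_variants),
            n_template_variants = as.integer(n_template_variants),
            template_bias_fraction = template_bias_fraction,
            template_mutation_rate = template_mutation_rate,
            abundance_skew = abundance_skew,
            indel_aberration_rate = indel_aberration_rate,
            colony_count = as.integer(colony_count))
  if (m$n_true_variants < 1L) stop_("n_true_variants must be >= 1")
  if (m$n_template_variants < 0L ||
      m$n_template_variants > m$n_true_variants)
    stop_("n_template_variants must lie in [0, n_true_variants]")
  rates <- c(m$template_bias_fraction, m$template_mutation_rate,
             m$indel_aberration_rate)
  if (any(rates < 0 | rates > 1)) stop_("rates must lie in [0, 1]")
  if (m$abundance_skew < 0) stop_("abundance_skew must be >= 0")
  if (m$template_bias_fraction > 0 && m$n_template_variants == 0L)
    stop_("template_bias_fraction > 0 requires n_template_variants >= 1")
  if (m$colony_count < 1L) stop_("colony_count must be >= 1")
  class(m) <- "library_model"
  m
}

#' Preset library models
#'
#' Three named presets emulating the headline library types: `"wpa"`, a
#' heavily template-biased whole-plasmid-amplification library (half the
#' read mass template-like, strong jackpot skew); `"overflap"`, an
#' essentially unbiased library with a trace template contamination; and
#' `"overflap-asym"`, a fully unbiased, low-skew library.
#'
#' @param name One of `"wpa"`, `"overflap"`, `"overflap-asym"`.
#' @return A [library_model()].
#' @export
library_preset <- function(name = c("wpa", "overflap", "overflap-asym")) {
  name <- match.arg(name)
  switch(name,
    "wpa" = library_model(n_true_variants = 1000L,
                          n_template_variants = 8L,
                          template_bias_fraction = 0.5,
                          template_mutation_rate = 0.02,
                          abundance_skew = 2.5,
                          indel_aberration_rate = 0.02,
                          colony_count = 3802L),
    "overflap" = library_model(n_true_variants = 5000L,
                               n_template_variants = 1L,
                               template_bias_fraction = 3e-5,
                               template_mutation_rate = 0.02,
                               abundance_skew = 1.2,
                               indel_aberration_rate = 0.01,
                               colony_count = 4534L),
    "overflap-asym" = library_model(n_true_variants = 50000L,
                                    n_template_variants = 0L,
                                    template_bias_fraction = 0,
                                    template_mutation_rate = 0.02,
                                    abundance_skew = 0.8,
                                    indel_aberration_rate = 0.005,
                                    colony_count = 4865L))
}

#' Sequencing error model
#'
#' Independent per-base substitutions plus single-base indels within
#' homopolymer runs of length three or more, emulating the dominant
#' artefact of semiconductor sequencing. Anchor regions receive the same
#' error process as the insert.
#'
#' @param substitution_rate Per-base substitution probability
#'   (default 0.005).
#' @param homopolymer_indel_rate Per-run (length >= 3) probability of a
#'   single-base insertion or deletion (default 0.01).
#' @return An object of class `error_model`.
#' @export
error_model <- function(substitution_rate = 0.005,
                        homopolymer_indel_rate = 0.01) {
  m <- list(substitution_rate = substitution_rate,
            homopolymer_indel_rate = homopolymer_indel_rate)
  if (any(unlist(m) < 0 | unlist(m) > 1)) stop_("rates must lie in [0, 1]")
  class(m) <- "error_model"
  m
}

# per-stage substream seeds derived deterministically from a master seed
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage * 10007) %% 2147483647)
}

random_inserts <- function(n, len) {
  if (n == 0L) return(character())
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  apply(m, 1L, paste0, collapse = "")
}

mutate_bases <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste0(ch, collapse = "")
}

apply_length_aberration <- function(seq) {
  # whole-codon changes with prob 0.8, frame-breaking otherwise; deletion
  # or duplication of a contiguous segment with equal probability
  size <- if (stats::runif(1) < 0.8) 3L * sample(1:2, 1L) else
    sample(c(1L, 2L, 4L), 1L)
  n <- nchar(seq)
  if (stats::runif(1) < 0.5 && n > size) {            # deletion
    at <- sample(n - size + 1L, 1L)
    paste0(substr(seq, 1L, at - 1L), substring(seq, at + size))
  } else {                                            # duplication
    at <- sample(max(n - size + 1L, 1L), 1L)
    seg <- substr(seq, at, min(at + size - 1L, n))
    paste0(substr(seq, 1L, at - 1L), seg, substring(seq, at))
  }
}

#' Draw the true variant pool of a simulated library
#'
#' Template-like variants are the template insert with i.i.d.
#' substitutions; random variants are uniform A/C/G/T strings of the
#' designed length, with length aberrations at the configured rate.
#' Abundances are drawn log-normally and normalized so the template-like
#' pool's total mass equals `template_bias_fraction` exactly. Fully
#' reproducible from `seed`.
#'
#' @param model A [library_model()].
#' @param spec A [template_spec()].
#' @param seed Integer master seed.
#' @return data.frame of class `truth_table`: `variant_id`, `insert`
#'   (nucleotides, flanks excluded), `origin` (`template_like` or
#'   `random`) and `abundance` (sums to 1).
#' @export
generate_truth <- function(model, spec, seed = 1L) {
  stopifnot(inherits(model, "library_model"), inherits(spec, "template_spec"))
  withr::with_seed(derive_seed(seed, 1L), {
    nt <- model$n_template_variants
    nr <- model$n_true_variants - nt
    tmpl <- vapply(seq_len(nt), function(i)
      mutate_bases(spec$template_insert, model$template_mutation_rate), "")
    rand <- random_inserts(nr, spec$designed_random_length)
    if (nr > 0L && model$indel_aberration_rate > 0) {
      ab <- which(stats::runif(nr) < model$indel_aberration_rate)
      for (i in ab) rand[i] <- apply_length_aberration(rand[i])
    }
    a <- if (model$abundance_skew > 0)
      stats::rlnorm(model$n_true_variants, 0, model$abundance_skew)
    else rep(1, model$n_true_variants)
    origin <- rep(c("template_like", "random"), c(nt, nr))
    bias <- model$template_bias_fraction
    if (nt > 0L && nr > 0L) {
      a[origin == "template_like"] <-
        a[origin == "template_like"] / sum(a[origin == "template_like"]) * bias
      a[origin == "random"] <-
        a[origin == "random"] / sum(a[origin == "random"]) * (1 - bias)
    } else {
      a <- a / sum(a)
    }
    out <- data.frame(
      variant_id = sprintf("v%05d", seq_len(model$n_true_variants)),
      insert = c(tmpl, rand), origin = origin, abundance = a,
      stringsAsFactors = FALSE)
    class(out) <- c("truth_table", "data.frame")
    out
  })
}

# vectorized substitution errors over a read set, via one flat integer
# vector of base codes
apply_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  big <- utf8ToInt(paste0(seqs, collapse = ""))
  codes <- utf8ToInt("ACGT")
  idx <- match(big, codes)                       # 1..4
  hit <- which(stats::runif(length(big)) < rate & !is.na(idx))
  if (length(hit)) {
    shift <- sample(1:3, length(hit), replace = TRUE)
    big[hit] <- codes[((idx[hit] - 1L + shift) %% 4L) + 1L]
  }
  starts <- cumsum(c(1L, lens[-length(lens)]))
  substring(intToUtf8(big), starts, starts + lens - 1L)
}

# single-base indels within homopolymer runs >= 3, per-run Bernoulli
apply_homopolymer_indels <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  big <- utf8ToInt(paste0(seqs, collapse = "\n"))
  r <- rle(big)
  run_end <- cumsum(r$lengths)
  cand <- which(r$lengths >= 3L & r$values != 10L)   # 10 = newline separator
  if (!length(cand)) return(seqs)
  ev <- cand[stats::runif(length(cand)) < rate]
  if (!length(ev)) return(seqs)
  bnd <- c(0L, cumsum(lens + 1L))                # read k spans bnd[k]+1..bnd[k+1]-1
  read_of <- findInterval(run_end[ev], bnd, left.open = TRUE)
  pos_in_read <- run_end[ev] - bnd[read_of]      # last base of the run
  ins <- stats::runif(length(ev)) < 0.5
  for (k in order(read_of, -pos_in_read)) {
    i <- read_of[k]; p <- pos_in_read[k]
    s <- seqs[i]
    seqs[i] <- if (ins[k])
      paste0(substr(s, 1L, p), substr(s, p, p), substring(s, p + 1L))
    else paste0(substr(s, 1L, p - 1L), substring(s, p + 1L))
  }
  seqs
}

#' Simulate amplicon reads from a truth table
#'
#' Samples variants according to their true abundances, assembles each
#' read as upstream anchor + left flank + insert + right flank +
#' downstream anchor, applies substitution and homopolymer-indel
#' sequencing errors over the whole read (anchors included), and emits
#' roughly half of the reads reverse-complemented. Quality strings are a
#' constant `I`.
#'
#' @param truth A `truth_table` from [generate_truth()].
#' @param spec The [template_spec()] used to build the truth.
#' @param error_model An [error_model()].
#' @param n_reads Number of reads to draw (>= 1).
#' @param seed Integer master seed.
#' @return data.frame with `read_id`, `sequence`, `quality`, plus the
#'   provenance columns `variant_id` and `true_orientation`.
#' @export
generate_reads <- function(truth, spec, error_model = overflapr::error_model(),
                           n_reads, seed = 1L) {
  stopifnot(inherits(truth, "truth_table"), inherits(spec, "template_spec"))
  if (n_reads < 1L) stop_("n_reads must be >= 1")
  withr::with_seed(derive_seed(seed, 2L), {
    idx <- sample.int(nrow(truth), n_reads, replace = TRUE,
                      prob = truth$abundance)
    flip <- stats::runif(n_reads) < 0.5
    seqs <- paste0(spec$upstream_anchor, spec$left_flank,
                   truth$insert[idx], spec$right_flank,
                   spec$downstream_anchor)
    seqs <- apply_substitutions(seqs, error_model$substitution_rate)
    seqs <- apply_homopolymer_indels(seqs,
                                     error_model$homopolymer_indel_rate)
    if (any(flip)) seqs[flip] <- reverse_complement(seqs[flip])
    data.frame(
      read_id = sprintf("sim_%07d", seq_len(n_reads)),
      sequence = seqs,
      quality = strrep("I", nchar(seqs)),
      variant_id = truth$variant_id[idx],
      true_orientation = ifelse(flip, "reverse_complement", "forward"),
      stringsAsFactors = FALSE)
  })
}
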
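# Pipeline configuration for the bundled alpha-factor / alpha-MSH template.
# The extracted region is left_flank + randomized insert + right_flank,
# located between the two anchors; the template insert is the 39-nt
# alpha-MSH CDS the randomization replaces.
template:
  name: alphaFactor-alphaMSH
  upstream_anchor: AGAGAGGCTGAAGCA
  downstream_anchor: GCAGCATCT
  left_flank: TAC
  right_flank: TAA
  template_insert: TCTTATTCTATGGAACATTTTAGATGGGGTAAACCAGTT
  designed_random_length: 54
classifier:
  max_mismatches: 10
  max_gaps: 3
  match_score: 1
  mismatch_score: -1
  gap_score: -1
  inclusive_bounds: false
options:
  anchor_max_error_rate: 0.1
  search_both_orientations: true
  internal_stop_policy: keep_symbol
  collapse_level: peptide
  random_seed: 1
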
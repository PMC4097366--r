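# Demo pipeline configuration: a one-plate simulated screen with ten planted
# modifiers, analysed against the packaged toy interaction networks and the
# synthetic ten-gene demo ortholog table (human symbols illustrative only).
seed: 11
alpha: 0.05
min_conf: 0.900
degree_k: 2
policy: union
replicate_exclusion: false
simulate:
  n_genes: 384
  planted_sl: [G0101, G0102, G0103, G0104, G0105]
  planted_ss: [G0201, G0202, G0203, G0204, G0205]
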
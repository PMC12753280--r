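# Canonical archetype comparison: three decision-makers with priors 0.90,
# 0.50 and 0.10 review ten B-favoring trials under unbiased and
# confirmation-biased (w_disconfirming = 0.5) updating. Per-archetype
# likelihood ratios are the endpoint-calibrated constants.
name: archetype-comparison
seed: 1
archetypes:
  - name: aTSA Loyalist
    prior: 0.90
    lr: 0.72
  - name: Neutral Thinker
    prior: 0.50
    lr: 0.678
  - name: rTSA Advocate
    prior: 0.10
    lr: 0.80
stream:
  mode: fixed
  n_trials: 10
policy:
  w_confirming: 1.0
  w_disconfirming: 0.5
  threshold: 0.5
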
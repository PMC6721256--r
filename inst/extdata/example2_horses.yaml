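# Race-horse study: two groups of six horses, load ~80% of maximum, states
# pre-race (doubling as intact baseline), immediately post-race, and after a
# 1 h rest. Group g1 was characterised by the original investigators as
# robust, g2 as weak.
# The published index aggregates the UNWEIGHTED signed fractions (the S
# column in the source is per-group and is not applied to its printed A),
# so the fixture pins weighting: none. Per-group S values are kept in the
# printed-terms companion file; derive them from each group's pre-race cells
# with compute_stability(policy = "per_group").
# A semi-quantitative perspiration score in the source table was excluded
# from the analysis panel.
design: case3
weighting: none
recovery: include
stability_source:
  policy: per_group
  state: pre
parameters:
  - name: p95
    category: adaptive
    units: "uA (95% HbO2 release capacity)"
  - name: p50
    category: adaptive
    units: "uA (50% HbO2 release capacity)"
  - name: hemoglobin
    category: adaptive
    units: "g x 100 mL^-1"
  - name: heart_rate
    category: adaptive
    units: "beat x min^-1"
  - name: lactate
    category: homeostatic
    units: "mg x 100 mL^-1"
  - name: alkalinity
    category: homeostatic
    units: "mg x 100 mL^-1"
metadata:
  P: "functional status (robust vs weak horses)"
  Q: "race at ~80% of maximal intensity, 1 h recovery interval"
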
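# Rat swimming-load study, destructively sampled (each state measured on
# different animals). Group B: control untrained; C: control trained;
# D: eleutherosides untrained; E: eleutherosides trained. Rest measurements
# double as the pre-load state (the control rest column is also the intact
# baseline; treated groups had no separately measured intact baseline, and
# all published fractions are computed against rest).
# Stability coefficients are the published ones (derived from the control
# untrained rest cohort), supplied fixed so that index arithmetic is
# decoupled from their rounding.
design: case3
weighting: stability
recovery: exclude
stability_source:
  policy: supplied
  state: pre
  groups: [B]
  note: published values, derived from the control untrained rest cohort;
    recompute via compute_stability() on the group B pre cells
parameters:
  - name: hcs11
    category: adaptive
    units: "ug x 100 mL^-1"
    S: 0.778
  - name: hexokinase
    category: homeostatic
    units: "nM NADPH x mg protein^-1 x min^-1"
    S: 0.913
  - name: ammonia
    category: homeostatic
    units: "ug x 100 mL^-1"
    S: 0.893
  - name: glycogen
    category: homeostatic
    units: "mg x 100 g^-1"
    S: 0.694
  - name: lactate
    category: homeostatic
    units: "mmol x L^-1"
    S: 0.672
metadata:
  P: "14-day swim training and/or eleutheroside injections (5 mg/kg b.i.d.)"
  Q: "15-min swim with 6% body-weight load"
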
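# Canonical hippocampal wiring.
#
# Input/EC layer sizes and k are task dependent; default_architecture()
# overrides them per dataset.  Hidden-layer sizes follow human subfield
# ratios (DG 400, CA3 80, CA1 100).  DG/CA3 carry high set-point
# inhibition (k = 4 strongly active units, 1% of DG, 5% of CA3), CA1
# lower inhibition (k = 25).  gain is the logistic slope of the
# rate-code transfer function; floor is the leak bound on the
# inhibition level (units must exceed it to activate).
layers:
  - name: Input
    size: 27
    k: 5
    gain: 40
  - name: EC_in
    size: 27
    k: 5
    gain: 40
    floor: 0.5
  - name: EC_out
    size: 27
    k: 5
    gain: 60
    floor: 0.3
  - name: DG
    size: 400
    k: 4
    gain: 100
  - name: CA3
    size: 80
    k: 4
    gain: 100
  - name: CA1
    size: 100
    k: 25
    gain: 150
    floor: 0.1

# Projections.  strength is a fixed multiplicative scalar on the
# projection's (normalized) drive; gates are per-phase multipliers
# (unlisted phases default to 1): the theta-phase scheme inhibits
# CA3->CA1 at the simulated trough and EC_in->CA1 at the simulated
# peak.  wc_gain/wc_off parameterize sigmoidal weight-contrast
# enhancement; hebb mixes a CPCA Hebbian component into the update.
#
# The sparse trisynaptic input projections keep raw wide-initialized
# weights (wc_gain 1): their job is stable random pattern separation.
# The CA3 recurrent projection is a Hebbian auto-associator supporting
# cued pattern completion.  Binding and monosynaptic projections use
# contrast enhancement with an offset, so only consolidated
# (repeatedly reinforced) weight changes are expressed in the drive.
#
# The one-to-one EC_in->EC_out shortcut is wired but defaults to
# strength 0 so that output activity is carried by CA1 (see the
# methods vignette); EC_out->EC_in closes the big loop.
projections:
  - src: Input
    dst: EC_in
    type: one_to_one
    learnable: false
    weight: 1.0
  - src: EC_in
    dst: EC_out
    type: one_to_one
    learnable: false
    weight: 1.0
    strength: 0.0
  - src: EC_out
    dst: EC_in
    type: one_to_one
    learnable: false
    weight: 1.0
    strength: 0.6
  - src: EC_in
    dst: DG
    type: sparse
    frac: 0.25
    learnable: true
    pathway: TSP
    lr: 0.02
    wc_gain: 1
    wc_off: 1
    init: [0.25, 0.75]
  - src: EC_in
    dst: CA3
    type: sparse
    frac: 0.25
    learnable: true
    pathway: TSP
    lr: 0.02
    wc_gain: 1
    wc_off: 1
    init: [0.25, 0.75]
  - src: DG
    dst: CA3
    type: sparse
    frac: 0.05
    learnable: true
    pathway: TSP
    lr: 0.02
    wc_gain: 1
    wc_off: 1
    init: [0.25, 0.75]
  - src: CA3
    dst: CA3
    type: recurrent
    learnable: true
    pathway: TSP
    lr: 0.02
    hebb: 1.0
    strength: 2.5
    wc_gain: 10
    wc_off: 1.25
  - src: CA3
    dst: CA1
    type: full
    learnable: true
    pathway: TSP
    lr: 0.02
    wc_gain: 10
    wc_off: 1.25
    gates:
      trough: 0.0
  - src: EC_in
    dst: CA1
    type: full
    learnable: true
    pathway: MSP
    lr: 0.002
    wc_gain: 12
    wc_off: 1.25
    gates:
      peak: 0.0
  - src: CA1
    dst: EC_out
    type: full
    learnable: true
    pathway: MSP
    lr: 0.02
    lr_fixed: true
    wc_gain: 10
    wc_off: 1.25
  - src: EC_out
    dst: CA1
    type: full
    learnable: true
    pathway: MSP
    lr: 0.002
    wc_gain: 12
    wc_off: 1.25
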
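# Laminar schemes for the P0 mouse cortex: relative layer thickness and
# expected (NeuN-based) neuron proportions per layer, pia to white matter.
# The S2 L6 relative thickness of 0.867 as originally reported is an
# apparent typo (the row would be dominated by L6 and sums to 1.602); the
# default scheme uses the corrected 0.267, the verbatim value is kept under
# `thickness_verbatim` and can be requested explicitly.
layers: [MZ, CP, L5, L6, SP]
areas:
  M1:
    thickness: [0.079, 0.215, 0.276, 0.320, 0.107]
    neuron_proportion: [0.06, 0.29, 0.24, 0.34, 0.07]
  S1Bf:
    thickness: [0.070, 0.245, 0.301, 0.263, 0.088]
    neuron_proportion: [0.06, 0.33, 0.24, 0.31, 0.06]
  S2:
    thickness: [0.112, 0.218, 0.273, 0.267, 0.132]
    thickness_verbatim: [0.112, 0.218, 0.273, 0.867, 0.132]
    neuron_proportion: [0.08, 0.32, 0.22, 0.30, 0.09]
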
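# Default mixture specifications for the synthetic conformer pools.
# backbone: periodic (von Mises) mixture over (phi, psi); kappa is the
# angular concentration per axis. chi wells: wrapped-normal rotameric wells
# (gauche-/gauche+/trans). Weights must sum to 1.
default:
  backbone:
    modes:
      - {mu: [-63, -43], kappa: [20, 20], weight: 0.45}   # alpha
      - {mu: [-120, 130], kappa: [8, 8], weight: 0.35}    # beta
      - {mu: [-65, 145], kappa: [15, 15], weight: 0.20}   # PPII-like
  chi1: {means: [-60, 60, 180], weights: [0.50, 0.15, 0.35], sd: 12}
  chiN: {means: [-60, 60, 180], weights: [0.35, 0.15, 0.50], sd: 12}
GLY:
  backbone:
    modes:
      - {mu: [-80, 80], kappa: [4, 4], weight: 0.40}
      - {mu: [80, -80], kappa: [4, 4], weight: 0.40}
      - {mu: [180, 170], kappa: [2, 2], weight: 0.20}
PRO:
  backbone:
    modes:
      - {mu: [-62, -35], kappa: [40, 12], weight: 0.60}
      - {mu: [-62, 150], kappa: [40, 12], weight: 0.40}
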
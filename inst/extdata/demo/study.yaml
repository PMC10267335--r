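# Demo study config: per-genotype published activity summaries plus fully
# synthetic inputs (seeded, known ground truth) for every pipeline stage.
seed: 20230601

# Per-condition total CFTR-activated currents with baseline dIsc-Fsk either
# given directly or recoverable as total - increment.
worked_example: ussing_worked_example.csv

trajectory:
  - metric: lambda
    threshold: 5
    n_frames: 2000
    replicates: 3
    occupancy: 1.0
    mean_contact: 3.9
    sd_contact: 0.2
  - metric: sigma
    threshold: 7
    n_frames: 2000
    replicates: 3
    occupancy: 0.57
    mean_contact: 6.6
    sd_contact: 0.2
    mean_open: 10.7
    sd_open: 0.9

qpcr:
  allele_fractions: [0.5, 0.5]
  degradation: 0.5094
  ct_noise_sd: 0.1

ussing:
  baseline_condition: DMSO
  teer: 242.3
  teer_range: [188, 1250]
  tau: 10
  drift: 0.001
  noise_sd: 0.05
  plateau_window: 30
  conditions:
    - condition: DMSO
      potentiator: DMSO
      deltas:
        amiloride: -2.0
        forskolin: 3.45
        CFTRinh-172: -3.45
        ATP: 4.0
    - condition: IVA
      potentiator: IVA
      deltas:
        amiloride: -2.0
        IVA: 0.0
        forskolin: 3.30
        CFTRinh-172: -3.30
        ATP: 4.0
    - condition: ELX/TEZ+DMSO
      potentiator: DMSO
      deltas:
        amiloride: -2.0
        forskolin: 6.00
        CFTRinh-172: -6.00
        ATP: 4.0
    - condition: ELX/TEZ+IVA
      potentiator: IVA
      deltas:
        amiloride: -2.0
        IVA: 0.30
        forskolin: 5.43
        CFTRinh-172: -5.73
        ATP: 4.0

cbf:
  frequency: 5.43
  amplitude: 1.0
  noise_sd: 0.5
  frame_rate: 100
  duration: 4
  dims: [8, 8]
  cultures: 3
  fields_per_culture: 6
  band: [0.5, 30]
  physiological_range: [3.0, 11.1]

blot:
  levels:
    WT: 100
    untreated: 3.18
    IVA: 5.06
    ELX_TEZ: 11.92
    ETI: 9.90
  loads_ug: [20, 40, 40, 40, 40]
  control_noise_sd: 0.05
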
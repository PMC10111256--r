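# Standard study condition: 22 L glass stirred tank, 5 mg/mL mAb,
# 5x molar payload excess fed over 60 s.
kinetics:
  k1: 0.797        # per mM per s
  k2: 1.476        # per mM per s
  k3: 0.00155      # per s
  mab_mg_per_ml: 5
  molar_mass: 150000
  excess: 5
vessel:
  template: GST-2
  levels: 4
  rings: 3
  speed_rpm: 120
  re_anchor: 22141      # published Reynolds number at 60 rpm
  re_anchor_rpm: 60
feed:
  mode: constant-rate
  duration: 60          # s
  stock_concentration: 10  # mM
simulation:
  t_end: 300            # s
  output_grid: 0.25     # s
  seed: 1
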
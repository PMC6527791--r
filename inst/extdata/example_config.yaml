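# Example run configuration: transitional constant-inflow operating point
# in the idealized 76% constricted channel at desk scale (d = 1 m, water).
geometry:
  length: 4.0        # m
  width: 1.0         # m (reference diameter d)
  occlusion: 0.76    # NASCET-style fraction; throat = d * (1 - 0.76)
dx: 0.03125          # m (32 cells across the width)
dt: null             # auto from the advective CFL bound
end_time: 5.0        # s
washout: 1.0         # s discarded from statistics
nu: 7.2464e-4        # m^2/s -> inlet Reynolds number 1380
les:
  model: none        # none | smagorinsky | sigma | dynamic_smagorinsky
inlet:
  kind: constant
  mean_flow: 4.7124e+07  # mL/min -> mean inlet velocity 1 m/s at d = 1 m
stations: [-0.75, 0.0, 0.6, 1.2]
noise_amplitude: 0.01
seed: 1
snapshot_every: 0
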
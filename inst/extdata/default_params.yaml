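# Canonical default parameter set for the saliency-driven LIF/WTA simulator.
# Units are SI: volts, siemens, farads, seconds. The saliency map is
# dimensionless with features of order 1e-9; Ginput converts map units to
# amperes of input current. noise_ampl / noise_const are in map units.
lif:
  dt: 1.0e-4        # integration time step, s (0.1 ms)
  Eleak: 0.0        # leak reversal potential, V
  Eexc: 0.1         # excitatory reversal potential, V
  Einh: -0.02       # inhibitory reversal potential, V
  Gleak: 1.0e-8     # leak conductance, S
  Gexc: 1.0e-6      # excitatory coupling pulse (saliency field -> WTA), S
  Ginh: 0.0         # inhibitory conductance on the saliency field, S
  GinhDecay: 1.0    # decay time constant of inhibitory conductance, s
  Ginput: 0.05      # input conductance, S per map unit
  Vthresh: 1.0e-3   # firing threshold, V
  C: 1.0e-9         # membrane capacitance, F
wta:
  C: 5.0e-8         # WTA membrane capacitance, F
  Gleak: 1.0e-8     # WTA leak conductance, S
  Ginh: 1.0e-2      # WTA global inhibition, S (inert before the first spike)
noise:
  noise_ampl: 1.0e-17   # amplitude of random noise added to the map
  noise_const: 1.0e-14  # constant noise offset added to the map
  map_range: 1.0e-9     # output range of the saliency map
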
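# Example experiment configuration.  Any subset of keys may be given;
# everything unset falls back to the package defaults (see
# default_config()).  Unknown keys are rejected.
wing:
  E_mean: 3.0e+9
  gradient: gradient
  zeta: 2
kinematics:
  rotation_axis: yaw
  rotation_rate: 1.0
sspoc:
  n_iterations: 20
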
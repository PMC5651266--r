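# Standard four-sphere configuration: shell radii and conductivities of the
# classic concentric head model, with the skull divisor K = 20 preset.
model:
  radii: [7.9, 8.0, 8.5, 9.0]   # brain, CSF, skull, scalp
  units: cm
  sigma_brain: 0.33             # S/m; CSF = 5x, skull = 1/K, scalp = 1x
  skull_divisor: 20
series:
  n_max: 5000
  rel_tol: 1.0e-12
dipole:
  position: [0, 0, 7.8]         # 1 mm below the brain surface, on +z
  moment: [0, 0, 1.0e-7]        # radial, A m
output:
  units: uV
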
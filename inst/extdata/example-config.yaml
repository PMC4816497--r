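# Example configuration override for the cardioib CLI and build_model().
# Values not listed fall back to the chosen preset
# (cardioib::default_config()).
preset: desk-healthy
geometry:
  edge_length: 0.55
protocol:
  p_ed: 8        # end-diastolic pressure, mmHg
  p_es: 150      # end-systolic pressure, mmHg
estimation:
  target_esv: 61 # ml (cluster-scale reference target)
  tol: 0.05
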
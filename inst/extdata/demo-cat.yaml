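# Cat prism session analysed over a fixed pre-movement window with a
# bipolar LFP derivation.
mode: cat
cat:
  n_baseline: 40
  consecutive_hits_to_end: 30
  n_post: 10
neural:
  fs_raw: 1000
  channel_names: [p01, p16]
  neighbour_map: {}
window:
  mode: fixed
  fixed_start_ms: -400
  fixed_end_ms: -200
seed: 8
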
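# Small demonstration session: 30-trial blocks, 10-trial epochs,
# 1000 Hz synthetic acquisition. Run with:
#   betadapt run --config demo-human.yaml --seed 7 --out demo_out
mode: human
task:
  n_baseline: 30
  n_adaptation: 30
  n_washout: 30
  epoch_len: 10
neural:
  fs_raw: 1000
seed: 7
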
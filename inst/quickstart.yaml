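# Desk-scale end-to-end run: ~2,000 screened segments, width-x0.25 network,
# 20 Huber epochs. Usage:
#   Rscript inst/cli/ppgbp.R run-all --config inst/quickstart.yaml --out-dir quickstart-run
seed: 1
out_dir: quickstart-run
sim:
  n_records: 220
  duration_s: 30
  preset: uniform
train:
  epochs: 20
  batch_size: 128
  lr0: 0.01
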
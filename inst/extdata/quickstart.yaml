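# Quickstart pipeline configuration: oracle-noise detection mode over a
# small 60-episode dataset; completes on one CPU in a few minutes.
seed: 1
synthgen:
  n_episodes: 60
  n_train: 40
  balance: 0.5
  duration_s: 20
  fps: 12.5
detection:
  mode: oracle_noise
  noise:
    dropout_prob: 0.1
    clutter_rate: 0.5
    jitter_sd: 2
takeseq:
  T_fixed: 64
actionclf:
  hidden: 16
  epochs: 200
  lr: 0.05
  batch_size: 32
  rule:
    k_consecutive: 3
    proximity_min: 0.8
    pill_confidence_min: 0.5
eval:
  positive_class: medication
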
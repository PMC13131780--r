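# Example class-map: folds a dataset's native label ids into the unified
# multiclass id space. Vesicle (12) and membrane (13) ids drop to background.
mapping:
  1: 1
  2: 2
  3: 2
  4: 3
excluded:
  - 12
  - 13
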
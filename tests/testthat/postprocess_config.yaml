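command: postprocess
pred: /no/such/file.mrc
min_size: 5
connectivity: 18
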
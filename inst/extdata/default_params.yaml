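# Selected pipeline defaults: sliding-window segmentation parameters for
# the main and exosome-mutant datasets, the novelty filter, and the
# sensitivity gates.
window: 10
threshold_main: 27.36
threshold_rrp6: 12.96
stat: sum
min_len: 200
fpkm_threshold: 1
ratio_threshold: 2
alpha: 0.05
gate_raw_p: false
sut_min_fpkm: 1
dedup_min_frac: 0.5
universe: orf
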
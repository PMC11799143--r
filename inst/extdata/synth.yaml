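# Default-size synthetic behavioral dataset: three waiting-time groups,
# 40 participants each, 9 blocks x 40 trials.
n_per_group: 40
blocks: 9
trials_per_block: 40
seed: 1
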
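deletion: complete
model: K2P
rate: 0.0083
partition: metadata
groups: [carteri, ivonicus_yuna]
threshold: 0.8
block_size: 10
adults_only: yes
n_reps: 1000
seed: 42
outdir: results
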
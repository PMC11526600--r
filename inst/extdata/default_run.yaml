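# Full comparative study: five designs x ten scenarios at the slight
# positive correlation preset (r_max / 3), 10,000 replicates each.
designs: [top_pp, simon_pp, bop_pp, top_joint, itop_joint]
scenarios: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
correlation: pos1
reps: 10000
seed: 2024
output: results
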
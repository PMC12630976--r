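# Desk-scale preset: the full three-strategy meta-simulation on the hub5
# fixture network, sized to finish in minutes on one CPU. Scale n_truth /
# n_practitioner / n_sl up towards 1000 / 10 / 500 for study-scale runs.
fixture:
  name: hub5
learners: [hc, tabu, mmhc, pc.stable]
n_train: 200
n_test: 200
n_practitioner: 5
n_sl: 10
n_truth: 50
seed: 42
outdir: metasim-results
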
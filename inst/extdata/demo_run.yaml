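# demonstration pipeline configuration: three small groups, full chain
out_dir: results/demo_run
seed: 1
cohort:
  IPF: 4
  CHF: 4
  PN: 4
duration: 12
n_breaths: 3
folds: 2
tasks:
- IPF_vs_CHF
- IPF_vs_PN
classifiers:
- svm
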
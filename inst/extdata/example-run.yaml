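# Example pipeline configuration: simulate a small virtual cohort from
# the final model, fit it, and tabulate target attainment for two renal
# profiles. See ?runPipeline for all keys.
design:
  subjects: 40
saem:
  nBurn: 200
  nSmooth: 120
  nKernel: 3
stages: [simulate, fit, scenarios]
scenarios:
  - crcl: 90
    dose: 2000
  - crcl: 30
    dose: 2000
outdir: cefapk-run
seed: 1
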
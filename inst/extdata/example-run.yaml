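# Example run configuration for inst/scripts/ci-pipeline.R.
# Simulates a two-genotype diallel and analyses it end to end:
#   Rscript inst/scripts/ci-pipeline.R all --config example-run.yaml --out out
seed: 42
output_dir: ci-run
strict: false
simulate:
  kind: diallel
  genotypes: [A, B]
  theta: 0.8
  phi: 0.25
  replicates_per_cross: 10
mcmc:
  chains: 2
  iterations: 2000
  warmup: 500
model:
  fixed: inf*mgeno*fgeno
  day_intercepts: true
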
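# Example scenario: isocost coupling sweep of a two-reporter circuit
# sharing the host ribosome pool, with an idle orthogonal pool present.
host:
  s_ext: 10000.0
pools:
  - pool_id: o1
    omega_rho: 500.0
genes:
  - name: gfp
    omega: 100.0
    pool: host
  - name: rfp
    omega: 1.0
    pool: host
analysis:
  type: isocost
  induced: rfp
  constitutive: gfp
  omega_grid: {from: 0, to: 3, points: 8, log: true}
output_dir: ribopool-results
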
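scenario:
  n_population: 30000
  n_snps: 1500
  n_reference: 4000
  maf_range:
  - 0.05
  - 0.5
  ld_block_size: 5
  ld_rho:
  - 0.1
  - 0.7
  target_fraction: 0.1
  h2_exposure: 0.4
  h2_outcome: 0.3
  causal_alpha: 0.3
  prop_causal: 0.3
  participation_coefficients:
    education: 0.15
    health: 0.12
    smoking: -0.12
    age: 0.1
    bmi: -0.08
    education:health: 0.5
    education:smoking: -0.5
    age:health: 0.5
    bmi:health: -0.5
    education:age: 0.5
    smoking:health: -0.5
    income:health: 0.45
    obesity:age: -0.45
  loadings:
    .matrix: yes
    data:
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.7
    - 0.0
    - 0.0
    - 0.0
    - -0.3
    - 0.0
    - 0.4
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - -0.5
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - -0.4
    - 0.0
    - 0.0
    - -0.5
    - 0.6
    - 0.0
    nrow: 14
    rownames:
    - age
    - bmi
    - weight
    - height
    - education
    - household_size
    - sex
    - alcohol
    - smoking
    - employment
    - income
    - obesity
    - health
    - urbanisation
    colnames:
    - exposure
    - outcome
  seed: 1
sig_threshold: 0.0001
clump_kb: 250.0
clump_r2: 0.1
mr_clump_kb: 10000.0
mr_clump_r2: 0.001
mr_min_instruments: 10
n_blocks: 100
ldsc_window_kb: 1000.0
n_pcs: 5
folds: 5
seed: 1
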
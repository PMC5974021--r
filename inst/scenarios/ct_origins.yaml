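name: ct_origins
generation_time: 25.0
sample_sizes:
  TK: 150
  AA: 150
  CT: 210
priors:
  demic:
  - name: N_TK
    dist: loguniform
    min: 100.0
    max: 100000.0
  - name: N_AA
    dist: loguniform
    min: 100.0
    max: 100000.0
  - name: N_CT
    dist: loguniform
    min: 100.0
    max: 100000.0
  - name: r_TK
    dist: uniform
    min: 0.0
    max: 0.001
  - name: r_AA
    dist: uniform
    min: 0.0
    max: 0.001
  - name: r_CT
    dist: uniform
    min: 0.0
    max: 0.001
  - name: T_CT
    dist: uniform
    min: 500.0
    max: 3000.0
  - name: T_ROOT
    dist: uniform
    min: 5000.0
    max: 30000.0
  cultural:
  - name: N_TK
    dist: loguniform
    min: 100.0
    max: 100000.0
  - name: N_AA
    dist: loguniform
    min: 100.0
    max: 100000.0
  - name: N_CT
    dist: loguniform
    min: 100.0
    max: 100000.0
  - name: r_TK
    dist: uniform
    min: 0.0
    max: 0.001
  - name: r_AA
    dist: uniform
    min: 0.0
    max: 0.001
  - name: r_CT
    dist: uniform
    min: 0.0
    max: 0.001
  - name: T_CT
    dist: uniform
    min: 500.0
    max: 3000.0
  - name: T_ROOT
    dist: uniform
    min: 5000.0
    max: 30000.0
  continuous:
  - name: N_TK
    dist: loguniform
    min: 100.0
    max: 100000.0
  - name: N_AA
    dist: loguniform
    min: 100.0
    max: 100000.0
  - name: N_CT
    dist: loguniform
    min: 100.0
    max: 100000.0
  - name: r_TK
    dist: uniform
    min: 0.0
    max: 0.001
  - name: r_AA
    dist: uniform
    min: 0.0
    max: 0.001
  - name: r_CT
    dist: uniform
    min: 0.0
    max: 0.001
  - name: T_CT
    dist: uniform
    min: 500.0
    max: 3000.0
  - name: T_ROOT
    dist: uniform
    min: 5000.0
    max: 30000.0
  - name: m
    dist: loguniform
    min: 1.0e-06
    max: 0.01
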
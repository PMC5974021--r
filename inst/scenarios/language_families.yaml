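name: language_families
generation_time: 25.0
sample_sizes:
  AA: 100
  AN: 100
  ST: 100
  TK: 100
priors:
  model1:
  - name: N_AA
    dist: loguniform
    min: 100.0
    max: 100000.0
  - name: N_AN
    dist: loguniform
    min: 100.0
    max: 100000.0
  - name: N_ST
    dist: loguniform
    min: 100.0
    max: 100000.0
  - name: N_TK
    dist: loguniform
    min: 100.0
    max: 100000.0
  - name: T1
    dist: uniform
    min: 3000.0
    max: 8000.0
  - name: DT2
    dist: uniform
    min: 500.0
    max: 8000.0
  - name: DT3
    dist: uniform
    min: 500.0
    max: 8000.0
  model2:
  - name: N_AA
    dist: loguniform
    min: 100.0
    max: 100000.0
  - name: N_AN
    dist: loguniform
    min: 100.0
    max: 100000.0
  - name: N_ST
    dist: loguniform
    min: 100.0
    max: 100000.0
  - name: N_TK
    dist: loguniform
    min: 100.0
    max: 100000.0
  - name: T1
    dist: uniform
    min: 3000.0
    max: 8000.0
  - name: DT2
    dist: uniform
    min: 500.0
    max: 8000.0
  - name: DT3
    dist: uniform
    min: 500.0
    max: 8000.0
  model3:
  - name: N_AA
    dist: loguniform
    min: 100.0
    max: 100000.0
  - name: N_AN
    dist: loguniform
    min: 100.0
    max: 100000.0
  - name: N_ST
    dist: loguniform
    min: 100.0
    max: 100000.0
  - name: N_TK
    dist: loguniform
    min: 100.0
    max: 100000.0
  - name: T1
    dist: uniform
    min: 3000.0
    max: 8000.0
  - name: DT2
    dist: uniform
    min: 500.0
    max: 8000.0
  - name: DT3
    dist: uniform
    min: 500.0
    max: 8000.0
  model4:
  - name: N_AA
    dist: loguniform
    min: 100.0
    max: 100000.0
  - name: N_AN
    dist: loguniform
    min: 100.0
    max: 100000.0
  - name: N_ST
    dist: loguniform
    min: 100.0
    max: 100000.0
  - name: N_TK
    dist: loguniform
    min: 100.0
    max: 100000.0
  - name: T1
    dist: uniform
    min: 3000.0
    max: 8000.0
  - name: DT2
    dist: uniform
    min: 500.0
    max: 8000.0
  - name: DT3
    dist: uniform
    min: 500.0
    max: 8000.0
  model5:
  - name: N_AA
    dist: loguniform
    min: 100.0
    max: 100000.0
  - name: N_AN
    dist: loguniform
    min: 100.0
    max: 100000.0
  - name: N_ST
    dist: loguniform
    min: 100.0
    max: 100000.0
  - name: N_TK
    dist: loguniform
    min: 100.0
    max: 100000.0
  - name: T1
    dist: uniform
    min: 3000.0
    max: 8000.0
  - name: DT2
    dist: uniform
    min: 500.0
    max: 8000.0
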
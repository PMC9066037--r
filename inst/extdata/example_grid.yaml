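# Example scenario grid for four-path deltaF prediction: three trait
# settings x two proportion settings x three parent-number settings.
# Equilibrium variances and reliabilities are specific to the trait and
# proportion setting (stronger selection gives a slightly lower equilibrium
# variance and reliability).
version: 1
family_sizes:
  fmds: 4
  ffds: 4
  ffdd: 1.4
proportion_settings:
  - [0.05, 0.125, 0.01, 0.70]
  - [0.01, 0.05, 0.01, 0.70]
parent_settings:
  - [20, 50, 100, 7000]
  - [40, 100, 200, 14000]
  - [60, 150, 300, 21000]
trait_settings:
  - name: "single-trait h2=0.3"
    equilibrium:
      - proportions: [0.05, 0.125, 0.01, 0.70]
        sigma2_m: 0.2200
        sigma2_f: 0.2367
        r2_m: 0.4164
        r2_f: 0.4577
      - proportions: [0.01, 0.05, 0.01, 0.70]
        sigma2_m: 0.2190
        sigma2_f: 0.2365
        r2_m: 0.4138
        r2_f: 0.4571
  - name: "single-trait h2=0.1"
    equilibrium:
      - proportions: [0.05, 0.125, 0.01, 0.70]
        sigma2_m: 0.0774
        sigma2_f: 0.0806
        r2_m: 0.3329
        r2_f: 0.3590
      - proportions: [0.01, 0.05, 0.01, 0.70]
        sigma2_m: 0.0771
        sigma2_f: 0.0802
        r2_m: 0.3304
        r2_f: 0.3563
  - name: "index 1:1"
    equilibrium:
      - proportions: [0.05, 0.125, 0.01, 0.70]
        sigma2_m: 0.4040
        sigma2_f: 0.4225
        r2_m: 0.3861
        r2_f: 0.4015
      - proportions: [0.01, 0.05, 0.01, 0.70]
        sigma2_m: 0.4020
        sigma2_f: 0.4202
        r2_m: 0.3846
        r2_f: 0.3998
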
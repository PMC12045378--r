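# Harsh-environment competition experiment (relative group fitness):
# 10 all-A and 10 all-B groups under frequent group death.
model:
  K: 10
  Kg: 70
  mu: 0.7
  a: 0.9
  b: 4
  mode: relative
  T: 3000
  seed: 42
init:
  n_A: 10
  n_B: 10
experiment:
  M: 50
  statistic: group
biofilm:
  dim: 3
  K_BF: 500
  L: 0.1
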
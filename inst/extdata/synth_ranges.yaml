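water:
  T1:
  - 1.5
  - 2.2
  T2:
  - 0.03
  - 0.07
amide:
  fs:
  - 0.0002
  - 0.003
  ksw:
  - 10.0
  - 150.0
  T2s:
  - 0.005
  - 0.03
  delta: 3.5
noe16:
  fs:
  - 0.0002
  - 0.002
  ksw:
  - 10.0
  - 50.0
  T2s:
  - 0.001
  - 0.005
  delta: -1.6
noe35:
  fs:
  - 0.002
  - 0.02
  ksw:
  - 10.0
  - 50.0
  T2s:
  - 0.0002
  - 0.001
  delta: -3.5
r_amines:
- 0.2
- 3.0
r_MT:
- 0.2
- 3.0
R1M: 1.0
noise_sd: 0.01
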
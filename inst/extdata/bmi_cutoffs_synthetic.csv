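age,sex,overweight,obese
8,male,18.4,21.6
9,male,19.1,22.8
10,male,19.8,24.0
11,male,20.6,25.1
12,male,21.2,26.0
8,female,18.3,21.6
9,female,19.1,22.8
10,female,19.9,24.1
11,female,20.7,25.4
12,female,21.7,26.7
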
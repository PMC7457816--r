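m1 = 0.25
m2 = 0.20000000000000001
l1 = 0.53000000000000003
r1 = 0.27000000000000002
r2 = 0.23000000000000001
I1 = 0.0058520833333333341
I2 = 0.0035266666666666671
g = 9.8100000000000005
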
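g1: 365.0
C_over_pi: 58.4
C2_over_pi: 58.4
k_lat: 0.01005
t_ratio: 1.0
beta_h1: 67.5
h2: 37.6
S1: 0.2
Amax_over_pi: 247.2
Qr: 800.0
Cr: 400.0
beta: 0.75
Topt: 18.0
Ti_above: 21.0
Ti_below: 25.0
alpha2: 0.38
sink_off: no
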
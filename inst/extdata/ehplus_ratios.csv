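# E_m/(pH*u) ratio cells (mV/um = V/mm) for maize coleoptile segments,
# 4 treatments x 6 time points (minutes after treatment onset).
treatment,0,3,6,10,20,30
1 mM KCl + IAA,-0.199,-0.200,-0.192,-0.194,-0.208,-0.217
10 mM KCl,-0.182,-0.177,-0.175,-0.175,-0.176,-0.175
10 mM KCl + IAA,-0.109,-0.110,-0.108,-0.111,-0.116,-0.118
10 mM KCl + IAA + A-9-C,-0.144,-0.135,-0.138,-0.141,-0.140,-0.138
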
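# Growth-law coefficients (A t + B + C exp(-exp(-D (t - t_e)))) of two
# control fits for maize coleoptile relative elongation, dim green light,
# 25 C. Units: A, D in 1/s; B, C dimensionless; t_e in s.
source,A,se_A,B,se_B,C,se_C,D,se_D,t_e,se_t_e
control_1,14.0e-7,1.0e-7,0.0017,0.0006,0.087,0.005,12.6e-5,0.6e-5,22330,160
control_2,16.7e-7,0.7e-7,0.0002,0.0004,0.079,0.003,13.2e-5,0.5e-5,22080,180
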
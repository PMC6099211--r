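# point-dosimeter calibration factors per phantom depth:
# MOSFET calibration-factor range (mV/mGy) across the five dosimeters,
# TLD calibration factor (mGy/nC)
depth_cm,mosfet_cf_min,mosfet_cf_min_u,mosfet_cf_max,mosfet_cf_max_u,tld_k_mGy_per_nC,tld_k_u
0,1.64,0.06,1.75,0.06,0.0111,0.0001
1,1.81,0.06,1.95,0.06,0.0104,0.0001
2,2.07,0.07,2.16,0.08,0.0103,0.0001
3,2.46,0.10,2.60,0.09,0.0093,0.0001
4,2.68,0.10,2.82,0.12,0.0093,0.0001
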
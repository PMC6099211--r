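# GafChromic film calibration: dose(netDR) = a + b*x/ln(x), x = net reflectance change
# uncertainty model: u_percent(dose) = unc_a + unc_b * exp(-dose/unc_c)
depth_cm,a,b,unc_a,unc_b,unc_c
0,0.5676,-440.7870,4.1906,19.0195,2.1823
1,0.7748,-420.6050,4.4444,17.5723,1.9498
2,0.4796,-382.1020,4.0586,19.7632,1.8211
3,0.8338,-351.8470,4.1864,16.5703,2.0034
4,0.6517,-365.2600,3.9923,16.5250,2.0205
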
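organ,k_max_20C,alpha_MPa,g_res_20C,g_res_40C,a_MPa_inv,p50_MPa
flower,2.60,0.2,12.15,13.98,4.89,-3.57
leaf,8.57,0.65,4.68,5.01,1.53,-6.48
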
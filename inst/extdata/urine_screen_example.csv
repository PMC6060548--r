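mz,beta,or,wald_p,icc,rcal_beta_star,rcal_lo,rcal_hi,rcal_or
1399.8,0.324,1.38,0.032,0.458,0.707,0.06,1.35,2.03
1404.6,0.435,1.54,0.012,0.459,0.947,0.21,1.69,2.57
1553.8,-0.517,0.60,0.038,0.458,-1.129,-2.20,-0.06,0.32
1556.0,-0.757,0.47,0.018,0.458,-1.652,-3.03,-0.27,0.19
1688.0,-0.710,0.49,0.014,0.458,-1.549,-2.79,-0.30,0.21
1707.1,-0.928,0.40,0.008,0.458,-2.025,-3.53,-0.51,0.13
1755.7,-0.269,0.76,0.018,0.455,-0.591,-1.08,-0.10,0.55
1782.1,-0.767,0.46,0.040,0.458,-1.674,-3.28,-0.06,0.19
2416.3,-0.552,0.58,0.045,0.458,-1.205,-2.38,-0.02,0.30
2594.3,-0.543,0.58,0.029,0.458,-1.184,-2.25,-0.12,0.31
2797.8,-0.516,0.60,0.042,0.458,-1.126,-2.21,-0.04,0.32
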
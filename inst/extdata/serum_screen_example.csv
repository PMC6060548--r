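mz,beta,or,bh_p,icc,rcal_beta_star,rcal_lo,rcal_hi,rcal_or
1020.5,0.32,1.37,0.032,0.617,0.52,0.16,0.87,1.68
1192.4,-0.79,0.45,0.035,0.616,-1.29,-2.20,-0.38,0.28
1218.6,-0.95,0.39,0.017,0.616,-1.54,-2.46,-0.62,0.21
1367.8,-0.67,0.51,0.017,0.616,-1.08,-1.69,-0.47,0.34
1405.7,0.69,2.00,0.023,0.616,1.13,0.39,1.86,3.08
1418.6,0.32,1.38,0.017,0.616,0.52,0.20,0.84,1.68
1418.6,0.32,1.38,0.017,0.507,0.63,0.24,1.01,1.87
1440.6,1.03,2.80,0.028,0.616,1.67,0.54,2.80,5.30
1460.7,0.62,1.85,0.043,0.616,1.00,0.26,1.74,2.72
1504.9,-0.41,0.66,0.023,0.616,-0.67,-1.10,-0.23,0.51
1591.1,-0.65,0.52,0.017,0.616,-1.06,-1.68,-0.44,0.35
1605.9,-0.20,0.82,0.043,0.616,-0.32,-0.55,-0.08,0.73
1719.0,-0.49,0.61,0.021,0.616,-0.79,-1.30,-0.28,0.45
1739.9,0.26,1.30,0.017,0.616,0.42,0.17,0.67,1.52
1818.9,-1.21,0.30,0.014,0.616,-1.96,-3.02,-0.89,0.14
1826.7,-0.82,0.44,0.014,0.616,-1.34,-2.05,-0.63,0.26
1832.1,-1.66,0.19,0.003,0.616,-2.69,-3.90,-1.47,0.07
1835.0,-0.72,0.49,0.017,0.616,-1.17,-1.86,-0.46,0.31
1838.9,-0.50,0.61,0.036,0.616,-0.80,-1.37,-0.23,0.45
1847.0,-0.37,0.69,0.017,0.616,-0.60,-0.96,-0.24,0.55
1886.0,-0.79,0.45,0.024,0.616,-1.29,-2.14,-0.44,0.28
1895.9,0.30,1.35,0.017,0.616,0.48,0.20,0.76,1.62
1902.9,-0.98,0.38,0.028,0.616,-1.59,-2.66,-0.51,0.20
1919.2,-0.73,0.48,0.023,0.616,-1.18,-1.95,-0.41,0.31
1934.1,-0.32,0.72,0.017,0.616,-0.53,-0.83,-0.22,0.59
1968.9,-1.03,0.36,0.017,0.616,-1.67,-2.71,-0.62,0.19
1977.1,-0.96,0.38,0.017,0.616,-1.55,-2.51,-0.59,0.21
1980.2,-1.01,0.36,0.017,0.616,-1.65,-2.67,-0.62,0.19
1984.5,-0.64,0.53,0.017,0.616,-1.04,-1.63,-0.44,0.35
1994.9,-1.53,0.22,0.012,0.616,-2.48,-3.75,-1.20,0.08
2006.3,-0.26,0.77,0.017,0.616,-0.43,-0.70,-0.16,0.65
2037.1,-0.82,0.44,0.032,0.616,-1.33,-2.25,-0.40,0.27
3156.6,0.33,1.39,0.043,0.616,0.54,0.14,0.93,1.71
3272.6,0.52,1.69,0.029,0.616,0.85,0.27,1.43,2.34
3681.0,0.59,1.80,0.043,0.616,0.95,0.25,1.65,2.59
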
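conc_mg_g,time_days,To_C,Ea_kJ_mol,PV_meqO2_kg,TBA
0,0,239.48,91.21,2.42,0.0210
0.25,0,238.93,100.46,2.30,0.0191
0.52,0,239.38,99.97,2.46,0.0191
1.01,0,240.75,100.47,2.33,0.0202
1.48,0,240.03,98.90,2.35,0.0270
2.01,0,240.85,104.62,2.57,0.0307
3.07,0,240.93,101.37,2.64,0.0350
3.97,0,241.19,106.07,2.39,0.0368
0,10,238.32,86.89,6.71,0.0245
0.24,10,245.82,86.30,6.71,0.0305
0.48,10,246.86,85.43,7.34,0.0310
0.97,10,246.61,94.59,6.38,0.0289
1.29,10,246.03,95.01,5.88,0.0344
1.97,10,246.61,102.96,6.57,0.0372
2.96,10,245.83,100.65,6.48,0.0418
3.82,10,244.58,108.72,5.39,0.0396
0,30,232.46,94.57,13.86,0.0439
0.23,30,234.83,100.39,13.62,0.0446
0.45,30,239.77,101.56,13.41,0.0422
0.87,30,239.08,101.48,12.22,0.0419
1.27,30,235.78,101.38,13.48,0.0434
1.80,30,235.61,101.20,12.08,0.0456
2.74,30,234.96,100.42,12.15,0.0449
3.78,30,234.64,99.48,11.97,0.0460
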
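set,constituent,n,bias,sep,sep_c,slope,rsq_v,rpd,sd_val
corn_stover,moisture,31,-0.048,0.435,0.439,0.984,0.854,2.644,1.15
wheat_straw,moisture,23,0.028,0.377,0.385,0.903,0.896,3.024,1.14
corn_stover,cp,28,-0.102,0.342,0.333,1.037,0.918,3.392,1.16
wheat_straw,cp,26,-0.034,0.235,0.237,1.018,0.927,3.702,0.87
corn_stover,ndf,25,-0.426,2.103,2.102,0.925,0.860,2.620,5.51
wheat_straw,ndf,21,1.275,2.423,2.112,0.931,0.828,2.072,5.02
corn_stover,adf,29,-0.213,1.739,1.756,0.944,0.779,2.133,3.71
wheat_straw,adf,20,0.781,2.772,2.729,1.252,0.677,1.663,4.61
corn_stover,adl,29,-0.566,1.254,1.139,0.471,0.125,0.893,1.12
wheat_straw,adl,26,0.392,1.299,1.263,0.841,0.355,1.201,1.56
corn_stover,hemicellulose,26,-0.519,1.643,1.590,1.073,0.696,1.747,2.87
wheat_straw,hemicellulose,24,0.364,2.550,2.578,1.134,0.232,1.153,2.94
combined,moisture,56,-0.035,0.621,0.626,0.769,0.780,1.868,1.16
combined,cp,55,-0.004,0.195,0.197,1.017,0.979,6.872,1.34
combined,ndf,56,0.464,4.104,4.114,0.977,0.795,2.210,9.07
combined,adf,55,-0.042,2.563,2.586,1.092,0.871,2.751,7.05
combined,adl,58,0.079,1.067,1.074,1.018,0.801,2.259,2.41
combined,hemicellulose,52,-0.484,2.618,2.598,0.634,0.242,1.085,2.84
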
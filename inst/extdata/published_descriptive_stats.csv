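set,subset,constituent,n,min,max,mean,sd,cv
corn_stover,calibration,moisture,121,3.01,7.41,5.35,1.14,21.31
corn_stover,validation,moisture,31,3.12,7.31,5.36,1.15,21.43
wheat_straw,calibration,moisture,105,2.68,7.05,4.62,1.10,23.79
wheat_straw,validation,moisture,23,2.75,6.94,4.52,1.14,25.19
corn_stover,calibration,cp,123,2.15,10.15,5.18,1.34,25.88
corn_stover,validation,cp,28,2.63,7.19,4.91,1.16,23.52
wheat_straw,calibration,cp,105,1.52,6.75,3.36,0.94,28.14
wheat_straw,validation,cp,26,1.62,5.11,3.27,0.87,26.72
corn_stover,calibration,ndf,122,43.73,80.71,63.97,6.21,9.70
corn_stover,validation,ndf,25,48.93,70.36,62.29,5.51,8.84
wheat_straw,calibration,ndf,105,64.64,87.81,77.27,5.94,7.69
wheat_straw,validation,ndf,21,67.86,86.83,78.52,5.02,6.40
corn_stover,calibration,adf,122,23.36,66.57,36.28,4.71,12.99
corn_stover,validation,adf,29,26.69,42.54,35.54,3.71,10.45
wheat_straw,calibration,adf,105,35.73,58.72,46.79,4.98,10.64
wheat_straw,validation,adf,20,39.49,56.78,48.22,4.61,9.56
corn_stover,calibration,adl,121,1.17,10.70,3.26,1.61,49.46
corn_stover,validation,adl,29,1.35,5.79,2.94,1.12,38.12
wheat_straw,calibration,adl,105,4.34,9.93,6.92,1.55,22.34
wheat_straw,validation,adl,26,4.40,9.59,6.93,1.56,22.47
corn_stover,calibration,hemicellulose,122,13.53,37.47,27.78,3.58,12.90
corn_stover,validation,hemicellulose,26,16.26,30.55,27.29,2.87,10.51
wheat_straw,calibration,hemicellulose,105,23.34,44.91,30.58,3.67,12.00
wheat_straw,validation,hemicellulose,24,25.81,36.26,30.28,2.94,9.70
combined,calibration,moisture,225,2.68,7.41,5.00,1.18,23.60
combined,validation,moisture,56,2.75,7.31,4.98,1.16,23.69
combined,calibration,cp,225,1.52,10.15,4.30,1.47,34.19
combined,validation,cp,55,1.62,7.19,4.16,1.34,35.34
combined,calibration,ndf,223,43.73,87.81,70.20,8.99,12.81
combined,validation,ndf,56,48.93,86.47,70.01,9.07,12.84
combined,calibration,adf,224,23.36,66.57,41.10,7.18,17.47
combined,validation,adf,55,26.69,56.85,40.86,7.05,17.57
combined,calibration,adl,227,1.17,10.70,4.93,2.42,49.09
combined,validation,adl,58,1.35,9.59,4.92,2.41,49.19
combined,calibration,hemicellulose,226,13.53,44.91,29.07,3.87,13.31
combined,validation,hemicellulose,52,21.93,36.28,28.59,2.84,13.54
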
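metal,mean_ppm,sd_ppm,min_ppm,max_ppm,delta_ppm
As,15.65,10.02,5.96,155.54,-5.8
Cr,106.98,9.13,62.07,174.37,-29.4
Co,140.88,15.83,68.66,274.11,75.6
Cu,55.30,4.94,35.06,101.92,-26.9
Fe,375.82,42.74,179.71,731.27,283.6
Pb,19.31,12.81,6.93,196.38,-6.8
Mn,136.31,13.19,80.00,228.34,-16.7
Hg,10.46,0.86,6.75,18.81,-5.0
Mo,4.29,0.31,2.40,6.14,138.2
Ni,72.86,5.64,44.80,112.93,-24.7
Rb,4.77,0.53,2.40,8.28,8.1
Se,7.52,0.73,4.91,17.79,-4.3
Sr,8.32,1.64,4.77,22.81,-4.5
Zn,40.90,10.39,25.46,150.04,-25.0
Zr,15.78,1.70,6.66,27.13,0.0
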
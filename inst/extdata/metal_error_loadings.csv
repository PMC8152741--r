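metal,F1,F2,F3,F4
As,0.193,0.203,0.957,0.026
Cr,0.893,0.367,0.207,0.077
Co,0.416,0.835,0.273,0.071
Cu,0.960,0.157,0.178,-0.027
Fe,0.392,0.847,0.266,0.058
Pb,0.188,0.199,0.959,0.028
Mn,0.520,0.694,0.304,0.125
Hg,0.944,0.192,0.205,-0.010
Mo,0.191,0.119,0.085,0.958
Ni,0.942,0.244,0.165,-0.013
Rb,-0.419,0.779,0.042,-0.073
Se,0.852,0.202,0.441,0.009
Sr,0.892,-0.286,0.100,-0.073
Zn,0.640,0.212,0.702,-0.053
Zr,-0.242,-0.047,-0.056,0.952
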
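modality,organ,in_field_fraction,bath_fraction,bath_scale_gy,penumbra_gy,rbe_factor
3DCRT,heart,0.032,0.30,3.0,1.5,1.0
3DCRT,lung,0.18,0.30,4.0,1.5,1.0
3DCRT,breast,0.030,0.25,2.0,1.5,1.0
HT,heart,0.028,0.48,4.0,1.5,1.0
HT,lung,0.090,0.75,5.0,1.5,1.0
HT,breast,0.020,0.70,2.5,1.5,1.0
IMPT,heart,0.023,0.10,2.5,1.5,1.1
IMPT,lung,0.12,0.18,3.0,1.5,1.1
IMPT,breast,0.015,0.06,1.5,1.5,1.1
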
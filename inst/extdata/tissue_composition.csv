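tissue,f_ew,f_iw,f_nl,f_np,alb_ratio
adipose,0.135,0.017,0.7900,0.0020,0.049
muscle,0.118,0.630,0.0238,0.0072,0.064
liver,0.161,0.573,0.0348,0.0252,0.086
kidney,0.273,0.483,0.0207,0.0162,0.130
brain,0.162,0.620,0.0391,0.0533,0.048
heart,0.320,0.456,0.0115,0.0166,0.157
skin,0.382,0.291,0.0284,0.0111,0.277
spleen,0.207,0.579,0.0201,0.0198,0.097
lung,0.336,0.446,0.0030,0.0090,0.212
rest,0.282,0.475,0.0487,0.0163,0.158
uterus,0.282,0.475,0.0138,0.0111,0.158
placenta,0.300,0.450,0.0088,0.0120,0.150
fetal_tissue,0.300,0.520,0.0150,0.0100,0.100
plasma,0.945,0.000,0.0035,0.0023,1.000
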
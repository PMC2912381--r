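line,p_line,p_line_sex,p_line_male,p_line_female,pct_male,pct_female,category
BG00004,*,ns,**,ns,16.6,2.3,both sexes
BG00008,***,**,****,ns,21.1,0.1,male-specific
BG00010,****,ns,****,ns,22.1,8.0,both sexes
BG00028,****,****,****,ns,27.8,-1.2,male-specific
BG00037,***,*,ns,****,3.3,16.5,female-specific
BG00039,*,**,ns,***,-0.5,16.2,female-specific
BG00041,ns,**,***,ns,14.7,-5.8,male-specific
BG00042,****,***,****,ns,33.4,1.2,male-specific
BG00043,****,ns,****,****,27.2,16.7,both sexes
BG00080,*,ns,ns,**,7.7,6.9,both sexes
BG00106,****,ns,****,*,25.6,14.6,both sexes
BG00121,*,**,**,ns,9.3,-1.2,male-specific
BG00218,****,****,****,*,22.8,4.6,male-biased
BG00297,****,**,****,ns,23.8,5.6,male-specific
BG00336,****,ns,****,***,18.6,11.0,both sexes
BG00346,****,****,****,ns,26.8,1.5,male-specific
BG00472,**,*,****,ns,18.0,2.4,male-specific
BG00495,****,ns,****,****,32.7,22.9,both sexes
BG00528,****,***,ns,****,0.6,22.8,female-specific
BG00719,ns,**,*,*,5.5,-6.2,sex-antagonistic
BG00757,**,****,****,ns,26.8,-4.5,male-specific
BG00761,****,ns,**,****,14.0,15.3,both sexes
BG00767,****,**,*,****,5.8,22.6,female-biased
BG00817,*,**,***,ns,12.7,-1.7,male-specific
BG00864,ns,****,****,**,-14.9,14.4,sex-antagonistic
BG00890,**,*,***,ns,19.1,3.0,male-specific
BG00907,***,***,****,ns,26.7,0.6,male-specific
BG00915,****,*,****,ns,26.0,7.4,male-specific
BG01004,**,*,****,ns,18.0,1.5,male-specific
BG01030,****,****,ns,****,5.3,27.7,female-specific
BG01031,ns,**,**,ns,13.3,-8.4,male-specific
BG01042,ns,****,****,**,21.1,-9.8,sex-antagonistic
BG01085,**,*,****,ns,20.1,4.1,male-specific
BG01121,ns,*,**,ns,6.6,-5.0,male-specific
BG01283,****,*,****,ns,20.2,6.1,male-specific
BG01345,****,ns,****,****,21.5,21.0,both sexes
BG01403,****,*,*,****,7.1,20.4,female-biased
BG01540,ns,****,ns,****,-5.3,13.4,female-specific
BG01550,ns,**,*,mar,6.2,-11.6,sex-antagonistic
BG01551,*,ns,**,ns,10.0,0.6,both sexes
BG01553,***,*,****,ns,16.7,3.0,male-specific
BG01615,****,ns,****,*,22.0,11.8,both sexes
BG01677,****,ns,****,****,16.9,21.9,both sexes
BG01700,****,*,****,*,17.6,6.9,male-biased
BG01701,*,ns,*,mar,5.8,15.8,both sexes
BG01702,ns,**,*,ns,8.2,-7.0,male-specific
BG01710,*,ns,ns,*,3.2,7.2,both sexes
BG01878,***,****,ns,****,-6.1,24.9,female-specific
BG01918,mar,ns,*,ns,9.0,1.0,male-specific
BG01950,***,****,****,****,-29.8,15.9,sex-antagonistic
BG01976,*,****,*,****,-9.2,24.0,sex-antagonistic
BG02019,ns,****,ns,****,-6.7,14.0,female-specific
BG02039,***,ns,**,ns,10.7,7.3,both sexes
BG02049,****,*,ns,****,5.5,19.6,female-specific
BG02128,ns,*,ns,***,-0.7,10.7,female-specific
BG02257,****,ns,****,**,10.3,7.4,both sexes
BG02395,**,ns,*,ns,10.4,4.6,both sexes
BG02644,*,***,***,ns,12.9,-1.5,male-specific
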
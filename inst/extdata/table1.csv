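# Dimensions of five measured spreading states of a settling vesicle
# (conserved volume ~3000 um^3). Columns: state label, bottom contact area,
# cap height, enclosed volume.
state_id,bottom_area_um2,height_um,volume_um3
a,125.09,15.45,2988.40
b,243.84,12.75,2998.36
c,421.28,10.96,3000.60
d,549.88,9.41,3000.49
e,696.53,8.03,3010.90
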
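subject_id,side,x_mm,y_mm,z_mm,err_x_mm,err_y_mm,err_z_mm
MA26,RHS,111.4,136.9,27.2,0.5,0.7,0.5
MA26,LHS,89.9,137,27.2,0.1,0.7,0.5
MA27,RHS,87.4,157.7,26.5,0.1,0.1,0.8
MA27,LHS,112.4,157.3,26.4,0.1,0.1,0.1
V3,RHS,107.5,124.5,46.7,0.25,0.5,0.25
V3,LHS,84.8,132.7,48.7,0.25,0.5,0.1
Thursday,RHS,111.9,121.2,46.3,0.25,0.7,0.8
Thursday,LHS,91.7,119.8,45.6,0.1,0,0
ZR1,RHS,88.9,126.9,31.3,0.1,0.1,0.2
ZR1,LHS,112,127.2,31.3,0.3,0.25,0.1
ZR3,RHS,112.4,164.1,27.2,0.3,0.5,0.5
ZR3,LHS,89.7,163.4,27.2,0.3,0.8,0.1
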
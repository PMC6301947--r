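cell_id,frame,t_min,x_um,y_um
c1,0,0,0,0
c1,1,11,1,0
c1,2,22,2,0
c1,3,33,3,0
c1,4,44,4,0
c2,0,0,0,0
c2,1,11,3,0
c2,2,22,3,4
c3,0,0,0,0
c3,1,11,5,0
c3,2,22,0,0
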
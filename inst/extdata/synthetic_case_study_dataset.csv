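observable,time_h,value_pct,sd_pct
weight_loss,0,2.74191689429334,2
weight_loss,4,4.67673419052291,2
weight_loss,8,2.68711790238401,2
weight_loss,16,6.47635083780013,2
weight_loss,20,7.69949250200717,2
weight_loss,24,8.34483369644115,2
weight_loss,40,17.9810227763369,2
weight_loss,64,23.5461875385708,2
crystallinity,0,30.0745718018952,2
crystallinity,4,20.1374113710917,2
crystallinity,8,16.0282573876243,2
crystallinity,16,0.106354525018668,2
crystallinity,20,0.594158032187557,2
crystallinity,24,0.163210320520212,2
crystallinity,40,1.27901596748253,2
crystallinity,64,2.64024123150483,2
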
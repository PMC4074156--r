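gene,length_nt,status,best_ref,identity,tm_count
AgoIR2,1125,partial_C,BmorIR40a,0.46,1
AgoIR21a,1704,partial_N,SlitIR21a,0.39,5
AgoIR76b,1713,complete,DmelIR76b,0.44,4
AgoIR3,1569,complete,DmelIR60a,0.23,4
AgoIR4,1392,complete,BmorIR64a,0.32,1
AgoIR68a,2034,complete,SlitIR68a,0.42,4
AgoIR8a,2595,complete,BmorIR8a,0.61,3
AgoIR5,1992,complete,BmorIR87a,0.22,5
AgoIR75d.1,2202,complete,SlitIR75d,0.38,5
AgoIR75d.3,1986,complete,DmelIR75d,0.3,0
AgoIR6,2463,complete,DmelIR76a,0.27,3
AgoIR93a,1860,complete,BmorIR93a,0.53,4
AgoIR25a,2433,complete,BmorIR25a,0.66,3
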
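gene,length_nt,status,best_ref,identity,tm_count
AgoOrco,1383,complete,ApOR1,0.95,7
AgoOR2,1212,partial_N,ApOR2,0.843,6
AgoOR3,1146,complete,ApOR4,0.422,6
AgoOR4,1164,complete,ApOR4,0.801,7
AgoOR5,723,partial_M,ApOR5,0.505,6
AgoOR6,1308,complete,ApOR64,0.594,6
AgoOR7,1242,complete,ApOR32,0.498,9
AgoOR8,1108,pseudogene,ApOR32,0.444,6
AgoOR9,948,partial_M,ApOR9,0.53,3
AgoOR10,1119,complete,ApOR10,0.721,6
AgoOR11,933,partial_N,ApOR23,0.322,4
AgoOR12,1239,complete,ApOR43,0.561,6
AgoOR13,1068,pseudogene,ApOR43,0.68,8
AgoOR14,795,partial_NC,ApOR32,0.316,4
AgoOR15,1077,complete,ApOR23,0.373,6
AgoOR16,807,pseudogene,ApOR32,0.316,4
AgoOR17,984,partial_M,ApOR17,0.366,4
AgoOR18,450,partial_N,ApOR17,0.206,2
AgoOR19,654,partial_NC,ApOR22,0.44,3
AgoOR20,1383,complete,ApOR20,0.76,6
AgoOR21,1088,pseudogene,ApOR21,0.67,5
AgoOR22,534,partial_NC,ApOR22,0.343,4
AgoOR23,1293,complete,ApOR23,0.753,7
AgoOR24,1122,complete,ApOR24,0.573,5
AgoOR25,1068,complete,ApOR25,0.577,6
AgoOR26,1386,complete,ApOR25,0.566,8
AgoOR27,945,partial_N,ApOR23,0.333,3
AgoOR28,720,partial_M,ApOR32,0.301,4
AgoOR29,1338,complete,ApOR25,0.581,6
AgoOR30,1335,pseudogene,ApOR25,0.661,6
AgoOR31,1219,pseudogene,ApOR31,0.686,6
AgoOR32,801,partial_M,ApOR31,0.448,5
AgoOR33,849,partial_M,ApOR33,0.34,4
AgoOR34,909,partial_C,ApOR32,0.333,7
AgoOR35,1167,complete,ApOR35,0.563,6
AgoOR36,1174,pseudogene,ApOR35,0.402,6
AgoOR37,1155,complete,ApOR37,0.796,6
AgoOR38,1230,partial_N,ApOR38,0.695,7
AgoOR39,1146,complete,ApOR39,0.776,4
AgoOR40,540,partial_N,ApOR40,0.319,2
AgoOR41,1260,complete,ApOR38,0.724,7
AgoOR42,1288,pseudogene,ApOR42,0.721,7
AgoOR43,1257,complete,ApOR43,0.806,7
AgoOR44,1288,pseudogene,ApOR45,0.543,6
AgoOR45,1119,complete,ApOR45,0.485,6
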
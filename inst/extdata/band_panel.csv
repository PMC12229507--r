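name,lo,hi,assignment
480,480,480,other
720,720,720,nucleic_acid
750,750,750,other
752-760,752,760,protein
811,811,811,nucleic_acid
877,877,877,lipid
1003,1003,1003,protein
1081,1081,1081,nucleic_acid
1090,1090,1090,lipid
1180,1180,1180,nucleic_acid
1235-1240,1235,1240,protein
1297,1297,1297,lipid
1336,1336,1336,protein
1449,1449,1449,lipid
1580,1580,1580,nucleic_acid
1582,1582,1582,other
1605,1605,1605,other
1654-1660,1654,1660,protein
1660,1660,1660,lipid
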
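molecule,perceptual_class,perceptual_subclass,wavenumbers
Benzene,Aromatic,Strong,399;637;1084;1485;3189
Anthracene,Aromatic,Weak,615;826;1147;1446;3206
Thiofuran,Aromatic,Weak,538;758;1043;1424;3258
Furan,Roasted Coffee,,633;816;1011;1498;3311
Furan methanethiol,Roasted Coffee,,157;684;1025;1526;2650;3251
Naphthalene,Moth-ball,,151;441;842;1150;1515;3213
Tetralin,Moth-ball,,118;468;827;1147;1471;3080
Fluorene,Moth-ball,,137;463;871;1126;1456;3193
Heptanal,Fruity,,79;883;1287;1817;3046
N-amyl Butyrate,Fruity,,118;846;1157;1386;1780;3066
gamma-Octalactone,Fruity,,112;820;1263;1816;3066
Civetone,Musk,,240;1044;1377;3009
Moxalone,Musk,,292;993;1370;3029
Galaxoltide,Musk,,318;989;1373;3035
Helvelotide,Musk,,280;999;1359;3029
Benzyl Mercaptan,Garlicky,artificial,260;881;1091;1454;2585;3193
Allyl thiol,Garlicky,artificial,272;927;1313;1696;2602;3086
Dimethyl sulfide,Garlicky,artificial,226;885;1371;3051
Diallyl disulfide,Garlicky,natural,110;439;922;1254;1724;3070
Allicin,Garlicky,natural,120;382;958;1313;1692;3109
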
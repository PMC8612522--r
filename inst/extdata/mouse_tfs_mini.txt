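Onecut1
Onecut2
Onecut3
Pou2f2
Pou3f1
Zfhx2
Zfhx3
Zfhx4
Nfia
Nfib
Nfix
Neurod1
Neurod2
Neurod6
Sox2
Sox9
Pax3
Pax6
Pax7
Nkx2-2
Nkx6-1
Olig2
Irx3
Dbx1
Dbx2
Ascl1
Neurog1
Neurog2
Atoh1
Ptf1a
Lhx1
Lhx2
Lhx5
Isl1
Isl2
Phox2b
Tcf4
Zbtb20
Npas3
Thra
Hmga1
Hmga2
Lin28a
Lin28b
Nr6a1
Foxp1
Foxp2
Evx1
En1
Chx10
Gata2
Gata3
Tal1
Sim1
Bhlhe22
Prdm8
Pou4f1
Tlx3
Lbx1
Lmx1b
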
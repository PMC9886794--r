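residue	name	charge	polarity	hydropathy	size_class	volume_A3	kd_index
A	Ala	neutral	nonpolar	hydrophobic	tiny	88.6	1.8
R	Arg	positive	polar	hydrophilic	large	173.4	-4.5
N	Asn	neutral	polar	hydrophilic	small	114.1	-3.5
D	Asp	negative	polar	hydrophilic	small	111.1	-3.5
C	Cys	neutral	polar	hydrophobic	small	108.5	2.5
Q	Gln	neutral	polar	hydrophilic	medium	143.8	-3.5
E	Glu	negative	polar	hydrophilic	medium	138.4	-3.5
G	Gly	neutral	nonpolar	neutral	tiny	60.1	-0.4
H	His	positive	polar	hydrophilic	medium	153.2	-3.2
I	Ile	neutral	nonpolar	hydrophobic	large	166.7	4.5
L	Leu	neutral	nonpolar	hydrophobic	large	166.7	3.8
K	Lys	positive	polar	hydrophilic	large	168.6	-3.9
M	Met	neutral	nonpolar	hydrophobic	large	162.9	1.9
F	Phe	neutral	nonpolar	hydrophobic	large	189.9	2.8
P	Pro	neutral	nonpolar	hydrophilic	small	112.7	-1.6
S	Ser	neutral	polar	neutral	tiny	89.0	-0.8
T	Thr	neutral	polar	neutral	small	116.1	-0.7
W	Trp	neutral	nonpolar	neutral	large	227.8	-0.9
Y	Tyr	neutral	polar	hydrophilic	large	193.6	-1.3
V	Val	neutral	nonpolar	hydrophobic	medium	140.0	4.2
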
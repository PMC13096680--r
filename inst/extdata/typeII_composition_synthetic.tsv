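residue	count_per_TC
A	429
R	180
N	70
D	91
C	2
E	150
Q	140
G	1216
H	18
I	40
L	95
K	130
M	26
F	47
P	665
S	160
T	100
W	4
Y	18
V	67
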
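residue	count_per_TC
A	617
R	165
N	45
D	80
C	2
E	140
Q	123
G	1077
H	45
I	35
L	85
K	137
M	20
F	140
P	231
S	115
T	60
W	10
Y	31
V	75
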
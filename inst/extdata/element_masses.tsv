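element	monoisotopic_da	average_da
C	12.000000000	12.011
H	1.007825032	1.008
N	14.003074005	14.007
O	15.994914620	15.999
P	30.973761998	30.974
S	31.972071174	32.06
F	18.998403163	18.998
Cl	34.968852682	35.45
Br	78.918337600	79.904
I	126.904471900	126.904
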
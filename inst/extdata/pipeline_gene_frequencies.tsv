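gene	category	sample	hits_per_million
amoA	nitrogen_cycling	LC3	200.5
amoA	nitrogen_cycling	LC11	175.3
amoA	nitrogen_cycling	HC3	0.0
amoA	nitrogen_cycling	HC11	0.0
narB	nitrogen_cycling	LC3	0.0
narB	nitrogen_cycling	LC11	0.0
narB	nitrogen_cycling	HC3	0.0
narB	nitrogen_cycling	HC11	10.5
nasA	nitrogen_cycling	LC3	17.2
nasA	nitrogen_cycling	LC11	11.7
nasA	nitrogen_cycling	HC3	0.0
nasA	nitrogen_cycling	HC11	0.0
nifH	nitrogen_cycling	LC3	116.3
nifH	nitrogen_cycling	LC11	133.6
nifH	nitrogen_cycling	HC3	0.0
nifH	nitrogen_cycling	HC11	0.8
ureC	nitrogen_cycling	LC3	9.3
ureC	nitrogen_cycling	LC11	35.8
ureC	nitrogen_cycling	HC3	0.0
ureC	nitrogen_cycling	HC11	0.3
nirS	nitrogen_cycling	LC3	4.0
nirS	nitrogen_cycling	LC11	22.3
nirS	nitrogen_cycling	HC3	0.0
nirS	nitrogen_cycling	HC11	0.0
nirK	nitrogen_cycling	LC3	26.5
nirK	nitrogen_cycling	LC11	12.3
nirK	nitrogen_cycling	HC3	0.0
nirK	nitrogen_cycling	HC11	0.0
nosZ	nitrogen_cycling	LC3	331.5
nosZ	nitrogen_cycling	LC11	173.9
nosZ	nitrogen_cycling	HC3	1.6
nosZ	nitrogen_cycling	HC11	0.0
norB	nitrogen_cycling	LC3	506.8
norB	nitrogen_cycling	LC11	503.7
norB	nitrogen_cycling	HC3	0.0
norB	nitrogen_cycling	HC11	1.0
narG	nitrogen_cycling	LC3	798.2
narG	nitrogen_cycling	LC11	709.3
narG	nitrogen_cycling	HC3	1.6
narG	nitrogen_cycling	HC11	0.5
napA	nitrogen_cycling	LC3	393.6
napA	nitrogen_cycling	LC11	104.0
napA	nitrogen_cycling	HC3	0.8
napA	nitrogen_cycling	HC11	0.0
dsrA	sulfate_reduction	LC3	9.6
dsrA	sulfate_reduction	LC11	47.6
dsrA	sulfate_reduction	HC3	0.0
dsrA	sulfate_reduction	HC11	20.1
dsrB	sulfate_reduction	LC3	8.2
dsrB	sulfate_reduction	LC11	25.6
dsrB	sulfate_reduction	HC3	8.8
dsrB	sulfate_reduction	HC11	22.2
total_monooxygenases	aerobic_hydrocarbon	LC3	1331.8
total_monooxygenases	aerobic_hydrocarbon	LC11	1453.0
total_monooxygenases	aerobic_hydrocarbon	HC3	3.2
total_monooxygenases	aerobic_hydrocarbon	HC11	7.6
total_dioxygenases	aerobic_hydrocarbon	LC3	4262.0
total_dioxygenases	aerobic_hydrocarbon	LC11	2401.7
total_dioxygenases	aerobic_hydrocarbon	HC3	572.0
total_dioxygenases	aerobic_hydrocarbon	HC11	523.6
alkylsuccinate_synthase	anaerobic_hydrocarbon	LC3	0.0
alkylsuccinate_synthase	anaerobic_hydrocarbon	LC11	0.3
alkylsuccinate_synthase	anaerobic_hydrocarbon	HC3	1.6
alkylsuccinate_synthase	anaerobic_hydrocarbon	HC11	0.3
benzylsuccinate_synthase	anaerobic_hydrocarbon	LC3	0.0
benzylsuccinate_synthase	anaerobic_hydrocarbon	LC11	0.0
benzylsuccinate_synthase	anaerobic_hydrocarbon	HC3	0.0
benzylsuccinate_synthase	anaerobic_hydrocarbon	HC11	0.0
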
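# Residue-level coarse-grained bead parameters, provenance: CALVADOS2
# sigma_nm: bead diameter; lambda: stickiness in [0,1]; charge_e: net side-chain
# charge at neutral pH (His neutral by default); mass_gmol: residue mass.
code	sigma_nm	lambda	charge_e	mass_gmol
A	0.504	0.2743	0	71.07
R	0.656	0.7308	1	156.19
N	0.568	0.4256	0	114.10
D	0.558	0.0416	-1	115.09
C	0.548	0.5615	0	103.14
Q	0.602	0.3934	0	128.13
E	0.592	0.0007	-1	129.11
G	0.450	0.7059	0	57.05
H	0.608	0.4664	0	137.14
I	0.618	0.5424	0	113.16
L	0.618	0.6440	0	113.16
K	0.636	0.1790	1	128.17
M	0.618	0.5308	0	131.20
F	0.636	0.8672	0	147.18
P	0.556	0.3593	0	97.12
S	0.518	0.4625	0	87.08
T	0.562	0.3713	0	101.10
W	0.678	0.9894	0	186.21
Y	0.646	0.9775	0	163.18
V	0.586	0.2084	0	99.13
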
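id	name
FE4S4	[4Fe-4S] iron-sulfur cluster
NA1	Na+
CO2P	Co2+
MG	Mg2+
CU2	Cu2+
H2SE	hydrogen selenide
N2	nitrogen
H2	H2
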
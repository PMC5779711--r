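# Vendor product names mapped to canonical enzymes.
alias	canonical	vendor
BcuI	SpeI	Thermofisher
Eco32I	EcoRV	Thermofisher
EcoRI	EcoRI	Thermofisher
BamHI	BamHI	Thermofisher
HindIII	HindIII	Thermofisher
NotI	NotI	Thermofisher
XhoI	XhoI	Thermofisher
KpnI	KpnI	Thermofisher
PstI	PstI	Thermofisher
NcoI	NcoI	Thermofisher
NdeI	NdeI	Thermofisher
SalI	SalI	Thermofisher
XbaI	XbaI	Thermofisher
SmaI	SmaI	Thermofisher
BglII	BglII	Thermofisher
SacI	SacI	Thermofisher
Eco91I	BsaI	Thermofisher
SpeI	SpeI	NEB
NheI-HF	NheI	NEB
SpeI-HF	SpeI	NEB
EcoRI	EcoRI	NEB
EcoRI-HF	EcoRI	NEB
BamHI	BamHI	NEB
BamHI-HF	BamHI	NEB
HindIII	HindIII	NEB
HindIII-HF	HindIII	NEB
NotI-HF	NotI	NEB
XhoI	XhoI	NEB
BsaI-HFv2	BsaI	NEB
NdeI	NdeI	NEB
SalI-HF	SalI	NEB
KpnI-HF	KpnI	NEB
PstI-HF	PstI	NEB
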
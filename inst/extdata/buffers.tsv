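# Digestion buffer activity table (percent activity of each vendor product
# in each buffer). SYNTHETIC illustrative defaults for simulation and
# testing - not vendor-published values; edit or replace with your own
# vendor tables for real planning.
vendor	buffer	alias	activity
Thermofisher	B	BcuI	100
Thermofisher	G	BcuI	50
Thermofisher	O	BcuI	20
Thermofisher	R	BcuI	50
Thermofisher	Tango	BcuI	100
Thermofisher	B	EcoRI	50
Thermofisher	G	EcoRI	50
Thermofisher	O	EcoRI	100
Thermofisher	R	EcoRI	100
Thermofisher	Tango	EcoRI	50
Thermofisher	B	BamHI	100
Thermofisher	G	BamHI	50
Thermofisher	O	BamHI	50
Thermofisher	R	BamHI	100
Thermofisher	Tango	BamHI	75
Thermofisher	B	HindIII	50
Thermofisher	G	HindIII	50
Thermofisher	O	HindIII	50
Thermofisher	R	HindIII	100
Thermofisher	Tango	HindIII	100
Thermofisher	B	Eco32I	20
Thermofisher	G	Eco32I	50
Thermofisher	O	Eco32I	100
Thermofisher	R	Eco32I	100
Thermofisher	Tango	Eco32I	50
Thermofisher	B	NotI	0
Thermofisher	G	NotI	20
Thermofisher	O	NotI	100
Thermofisher	R	NotI	50
Thermofisher	Tango	NotI	20
Thermofisher	B	XhoI	75
Thermofisher	G	XhoI	50
Thermofisher	O	XhoI	50
Thermofisher	R	XhoI	100
Thermofisher	Tango	XhoI	75
NEB	rCutSmart	SpeI	100
NEB	NEB1.1	SpeI	75
NEB	NEB2.1	SpeI	100
NEB	NEB3.1	SpeI	50
NEB	rCutSmart	SpeI-HF	100
NEB	NEB1.1	SpeI-HF	25
NEB	NEB2.1	SpeI-HF	50
NEB	NEB3.1	SpeI-HF	10
NEB	rCutSmart	EcoRI	25
NEB	NEB1.1	EcoRI	25
NEB	NEB2.1	EcoRI	100
NEB	NEB3.1	EcoRI	50
NEB	rCutSmart	EcoRI-HF	100
NEB	NEB1.1	EcoRI-HF	10
NEB	NEB2.1	EcoRI-HF	100
NEB	NEB3.1	EcoRI-HF	10
NEB	rCutSmart	BamHI	100
NEB	NEB1.1	BamHI	75
NEB	NEB2.1	BamHI	100
NEB	NEB3.1	BamHI	100
NEB	rCutSmart	HindIII	50
NEB	NEB1.1	HindIII	25
NEB	NEB2.1	HindIII	100
NEB	NEB3.1	HindIII	50
NEB	rCutSmart	BsaI-HFv2	100
NEB	NEB1.1	BsaI-HFv2	25
NEB	NEB2.1	BsaI-HFv2	75
NEB	NEB3.1	BsaI-HFv2	25
NEB	rCutSmart	NotI-HF	100
NEB	NEB1.1	NotI-HF	25
NEB	NEB2.1	NotI-HF	50
NEB	NEB3.1	NotI-HF	25
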
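gene	hpo_ids
CACNA1A	HP:0001250,HP:0007359,HP:0000639,HP:0001332,HP:0012758
STXBP1	HP:0001250,HP:0002121,HP:0001252,HP:0012758,HP:0002353
SCN2A	HP:0001250,HP:0011153,HP:0001252,HP:0012758
KMT2A	HP:0012758,HP:0004322,HP:0011968,HP:0000486,HP:0000365
ARID1B	HP:0012758,HP:0011968,HP:0002019,HP:0001252,HP:0000678
ANKRD11	HP:0012758,HP:0004322,HP:0000678,HP:0000545
DDX3X	HP:0012758,HP:0001252,HP:0000486,HP:0002121
KDM5B	HP:0012758,HP:0011968,HP:0000365
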
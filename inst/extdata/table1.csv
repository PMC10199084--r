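compound_id,pubchem_cid,role,binding_energy
A1,132210508,analog,-9.35
A2,132210370,analog,-8.92
A3,132210409,analog,-8.56
A4,132210478,analog,-8.55
A5,132210549,analog,-8.31
A6,59876521,analog,-8.11
A7,59876529,analog,-8.10
AGP,5318517,parent,-7.95
Rofecoxib,5090,control,-8.17
Aspirin,2244,control,-5.61
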
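category,parameter,permissible_range,Rofecoxib,Aspirin,AGP,A1,A2,A3,A4,A5,A6,A7
Physicochemical,MW,100~600,314.06,180.04,350.21,334.21,320.2,334.21,320.2,388.19,376.19,362.21
Physicochemical,HA,<38,22,13,25,24,23,24,23,27,27,26
Physicochemical,nHA,0~12,4,4,5,4,4,4,4,4,6,5
Physicochemical,nHD,0~7,1,1,3,2,2,2,2,2,1,1
Physicochemical,TPSA,0~140,67.51,63.6,86.99,66.76,66.76,66.76,66.76,66.76,82.06,64.99
Physicochemical,logP,0~3,3.014,1.237,1.58,2.763,2.435,2.763,2.435,3.229,2.458,2.556
Medicinal chemistry,NPscore,-5~5,-0.256,0.122,3.02,2.793,2.936,2.793,2.936,2.224,2.591,2.741
Medicinal chemistry,Lipinski Rule,,Accepted,Accepted,Accepted,Accepted,Accepted,Accepted,Accepted,Accepted,Accepted,Accepted
Medicinal chemistry,Pfizer Rule,,Rejected,Accepted,Accepted,Accepted,Accepted,Accepted,Accepted,Rejected,Accepted,Accepted
Absorption,Caco-2 Permeability,>-5.15,-5.598,-5.062,-4.793,-4.604,-4.647,-4.604,-4.647,-4.665,-4.732,-4.822
Absorption,Pgp-inhibitor,0~0.3,0.01,0,0,0,0,0,0,0,0.001,0.002
Absorption,HIA,0~0.3,0.005,0.007,0.245,0.028,0.217,0.028,0.217,0.01,0.007,0.008
Absorption,F30,0~0.3,0.003,0.003,0.036,0.006,0.049,0.006,0.049,0.007,0.501,0.02
Distribution,PPB,<=0.90,0.99,0.59,0.30,0.57,0.52,0.57,0.52,0.73,0.43,0.47
Distribution,VD,0.04~20,0.626,0.234,0.612,0.811,0.885,0.811,0.885,0.803,0.839,0.997
Distribution,BBB Penetration,0~1,0.037,0.661,0.955,0.996,0.987,0.996,0.987,0.987,0.995,0.983
Distribution,Fu,>=0.05,0.02,0.61,0.67,0.52,0.54,0.52,0.54,0.31,0.63,0.55
Metabolism,CYP inhibitor,0~1,0.146,0.016,0.167,0.407,0.155,0.407,0.155,0.351,0.466,0.412
Metabolism,CYP substrate,0~1,0.358,0.114,0.219,0.283,0.252,0.283,0.252,0.32,0.26,0.246
Excretion,CL,band_desc:15;5,0.535,2.736,8.907,14.47,14.712,14.47,14.712,9.945,13.704,13.431
Excretion,T1/2,band:0;0.3;0.7;1,0.116,0.91,0.249,0.119,0.134,0.119,0.134,0.04,0.121,0.087
Toxicology,hERG Blockers,band:0;0.3;0.7;1,0.087,0.015,0.003,0.004,0.004,0.004,0.004,0.005,0.001,0.002
Toxicology,H-HT,band:0;0.3;0.7;1,0.592,0.258,0.012,0.017,0.017,0.017,0.017,0.029,0.012,0.015
Toxicology,AMES Toxicity,band:0;0.3;0.7;1,0.006,0.013,0.327,0.266,0.227,0.266,0.227,0.158,0.065,0.271
Toxicology,Skin Sensitization,band:0;0.3;0.7;1,0.048,0.511,0.026,0.018,0.022,0.018,0.022,0.018,0.032,0.023
Toxicology,IGC50,,3.199,2.661,4.909,4.825,4.967,4.825,4.967,5.002,5.28,5.257
Toxicology,LC50,,4.275,3.748,6.605,6.114,6.293,6.114,6.293,6.461,6.613,6.973
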
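name,x,y
Fp1,-0.247214,0.760845
Fpz,0,0.8
Fp2,0.247214,0.760845
AF7,-0.470228,0.647214
AF3,-0.229341,0.647567
AFz,0,0.6
AF4,0.229341,0.647567
AF8,0.470228,0.647214
F7,-0.647214,0.470228
F5,-0.479908,0.4807
F3,-0.31576,0.470632
F1,-0.15558,0.443071
Fz,0,0.4
F2,0.15558,0.443071
F4,0.31576,0.470632
F6,0.479908,0.4807
F8,0.647214,0.470228
FT7,-0.760845,0.247214
FC5,-0.568282,0.25752
FC3,-0.377061,0.251334
FC1,-0.187539,0.231631
FCz,0,0.2
FC2,0.187539,0.231631
FC4,0.377061,0.251334
FC6,0.568282,0.25752
FT8,0.760845,0.247214
T7,-0.8,0
C5,-0.6,0
C3,-0.4,0
C1,-0.2,0
Cz,0,0
C2,0.2,0
C4,0.4,0
C6,0.6,0
T8,0.8,0
TP7,-0.760845,-0.247214
CP5,-0.568282,-0.25752
CP3,-0.377061,-0.251334
CP1,-0.187539,-0.231631
CPz,0,-0.2
CP2,0.187539,-0.231631
CP4,0.377061,-0.251334
CP6,0.568282,-0.25752
TP8,0.760845,-0.247214
P7,-0.647214,-0.470228
P5,-0.479908,-0.4807
P3,-0.31576,-0.470632
P1,-0.15558,-0.443071
Pz,0,-0.4
P2,0.15558,-0.443071
P4,0.31576,-0.470632
P6,0.479908,-0.4807
P8,0.647214,-0.470228
PO7,-0.470228,-0.647214
PO5,-0.308616,-0.653214
PO3,-0.151366,-0.636626
POz,0,-0.6
PO4,0.151366,-0.636626
PO6,0.308616,-0.653214
PO8,0.470228,-0.647214
O1,-0.247214,-0.760845
Oz,0,-0.8
O2,0.247214,-0.760845
Iz,0,-1
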
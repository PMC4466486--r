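label	x	y
Fp1	-0.3	0.9
AF7	-0.8	0.7
AF3	-0.4	0.7
F1	-0.2	0.5
F3	-0.4	0.5
F5	-0.6	0.5
F7	-0.8	0.5
FT7	-0.8	0.25
FC5	-0.6	0.25
FC3	-0.4	0.25
FC1	-0.2	0.25
C1	-0.2	0
C3	-0.4	0
C5	-0.6	0
T7	-0.8	0
TP7	-0.8	-0.25
CP5	-0.6	-0.25
CP3	-0.4	-0.25
CP1	-0.2	-0.25
P1	-0.2	-0.5
P3	-0.4	-0.5
P5	-0.6	-0.5
P7	-0.8	-0.5
P9	-0.95	-0.5
PO7	-0.8	-0.7
PO3	-0.4	-0.7
O1	-0.2	-0.9
Iz	0	-1.05
Oz	0	-0.9
POz	0	-0.7
Pz	0	-0.5
CPz	0	-0.25
Fpz	0	0.9
Fp2	0.3	0.9
AF8	0.8	0.7
AF4	0.4	0.7
AFz	0	0.7
Fz	0	0.5
F2	0.2	0.5
F4	0.4	0.5
F6	0.6	0.5
F8	0.8	0.5
FT8	0.8	0.25
FC6	0.6	0.25
FC4	0.4	0.25
FC2	0.2	0.25
FCz	0	0.25
Cz	0	0
C2	0.2	0
C4	0.4	0
C6	0.6	0
T8	0.8	0
TP8	0.8	-0.25
CP6	0.6	-0.25
CP4	0.4	-0.25
CP2	0.2	-0.25
P2	0.2	-0.5
P4	0.4	-0.5
P6	0.6	-0.5
P8	0.8	-0.5
P10	0.95	-0.5
PO8	0.8	-0.7
PO4	0.4	-0.7
O2	0.2	-0.9
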
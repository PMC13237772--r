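sequence,start,end,kd_uM,kd_se_uM
DYLEKQQSAWPFL,16,28,3.80,0.20
DYLEKQQSAW,16,25,4.30,0.30
DYLEKQQSAWPFLKPVSL,16,33,4.50,0.20
YLEKQQSAWPFLKPVSL,17,33,4.90,0.20
YLEKQQSAW,17,25,4.40,0.30
YLEKQQSAWPFL,17,28,3.60,0.20
LEKQQSAWPFLKPVS,18,32,5.20,0.20
LEKQQSAWPFL,18,28,3.70,0.20
LEKQQSAW,18,25,4.40,0.30
LEKQQSAWPFLKPVSL,18,33,5.00,0.30
EKQQSAWPFLKPVSL,19,33,5.20,0.30
EKQQSAWPFL,19,28,3.40,0.10
KQQSAWPFLKPVSL,20,33,5.90,0.40
KQQSAWPFL,20,28,3.50,0.20
PFLKPVSL,26,33,6.20,0.20
SEAPDY,34,39,9.10,0.20
YDIIKEPTDI,40,49,5.00,0.60
YDIIKEPTDILT,40,51,4.40,0.20
YDIIKEPTDIL,40,50,4.70,0.30
YDIIKEPTD,40,48,7.00,1.20
DIIKEPTDILT,41,51,5.00,0.30
DIIKEPTDIL,41,50,6.50,0.80
IIKEPTDILT,42,51,8.70,1.10
IIKEPTDIL,42,50,10.0,1.7
IIKEPTDILTM,42,52,4.70,0.30
IIKEPTDI,42,49,30.5,6.1
IKEPTDIL,43,50,4.70,0.70
EPTDILTMR,45,53,6.30,0.50
PTDILTMRRKA,46,56,3.40,0.40
LKRMFDNCRL,71,80,2.40,0.40
KRMFDNCRL,72,80,2.30,0.40
KRMFDNC,72,78,3.00,1.20
RMFDNCRL,73,80,2.50,0.70
RLYNAPTTIY,79,88,6.10,0.20
YNAPTTIYF,81,89,7.10,0.40
IYFKYANE,87,94,3.30,0.40
YFKYANE,88,94,3.50,0.40
YFKYANEL,88,95,2.30,0.40
FKYANEL,89,95,2.90,0.70
FKYANELQT,89,97,2.40,0.60
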
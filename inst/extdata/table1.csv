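compound,site,day8,day14
Dxr2-001,Dxr2,109,93
Dxr2-017,Dxr2,70,57
Dxr2-054,Dxr2,79,112
Dxr2-055,Dxr2,99,115
Dxr2-069,Dxr2,108,75
FolC2-001,FolC2,108,87
FolC2-005,FolC2,105,101
FolC2-025,FolC2,93,109
FolC2-044,FolC2,96,73
FolC2-048,FolC2,87,120
FolC1-020,FolC1,107,97
FolC1-031,FolC1,80,85
FolC1-042,FolC1,105,102
FolC1-087,FolC1,107,94
FolC1-100,FolC1,98,96
Dxr1-005,Dxr1,106,90
Dxr1-021,Dxr1,101,80
Dxr1-026,Dxr1,100,128
Dxr1-070,Dxr1,96,97
Dxr1-083,Dxr1,97,93
TYLT-001,TYLT,117,103
TYLT-003,TYLT,97,94
TYLT-051,TYLT,84,103
TYLT-072,TYLT,88,104
TYLT-088,TYLT,101,112
FabG-033,FabG,102,94
FabG-035,FabG,113,105
FabG-036,FabG,106,100
FabG-045,FabG,97,103
FabG-073,FabG,97,92
PRT-009,PRT,111,101
PRT-031,PRT,106,97
PRT-044,PRT,101,93
PRT-051,PRT,93,119
PRT-P89,PRT,111,93
EPSP-023,EPSP,94,114
EPSP-044,EPSP,98,98
EPSP-065,EPSP,99,98
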
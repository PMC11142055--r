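compound_id,site,cell_line,concentration,ratio
Dxr2-017,Dxr2,HT116,5.7,0.69
Dxr2-017,Dxr2,HT29,5.7,0.03
Dxr2-017,Dxr2,MCF-7,5.7,0.39
Dxr2-017,Dxr2,MDAMB231,5.7,0.05
Dxr2-017,Dxr2,H226,5.7,0.12
Dxr2-017,Dxr2,A549,5.7,1.26
Dxr2-017,Dxr2,PC3-M,5.7,0.41
Dxr2-017,Dxr2,LNCaP,5.7,0.49
FolC2-001,FolC2,HT116,5.7,0.85
FolC2-001,FolC2,HT29,5.7,1.13
FolC2-001,FolC2,MCF-7,5.7,0.65
FolC2-001,FolC2,MDAMB231,5.7,0.81
FolC2-001,FolC2,H226,5.7,0.56
FolC2-001,FolC2,A549,5.7,0.99
FolC2-001,FolC2,PC3-M,5.7,0.96
FolC2-001,FolC2,LNCaP,5.7,0.82
FolC1-020,FolC1,HT116,5.7,0.88
FolC1-020,FolC1,HT29,5.7,0.69
FolC1-020,FolC1,MCF-7,5.7,0.08
FolC1-020,FolC1,MDAMB231,5.7,0.96
FolC1-020,FolC1,H226,5.7,0.96
FolC1-020,FolC1,A549,5.7,0.84
FolC1-020,FolC1,PC3-M,5.7,0.76
FolC1-020,FolC1,LNCaP,5.7,-
TYLT-072,TYLT,HT116,5.7,0.83
TYLT-072,TYLT,HT29,5.7,1.22
TYLT-072,TYLT,MCF-7,5.7,0.94
TYLT-072,TYLT,MDAMB231,5.7,0.95
TYLT-072,TYLT,H226,5.7,0.26
TYLT-072,TYLT,A549,5.7,0.99
TYLT-072,TYLT,PC3-M,5.7,1.02
TYLT-072,TYLT,LNCaP,5.7,-
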
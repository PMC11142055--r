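compound_id,site,cell_line,concentration,ratio
Dxr2-017,Dxr2,HT116,40,0.08
Dxr2-017,Dxr2,HT29,40,0.00
Dxr2-017,Dxr2,MCF-7,40,0.02
Dxr2-017,Dxr2,MDAMB231,40,0.00
Dxr2-017,Dxr2,H226,40,0.02
Dxr2-017,Dxr2,A549,40,0.07
Dxr2-017,Dxr2,PC3-M,40,0.00
Dxr2-017,Dxr2,LNCaP,40,0.05
Dxr2-055,Dxr2,HT116,40,0.63
Dxr2-055,Dxr2,HT29,40,0.00
Dxr2-055,Dxr2,MCF-7,40,0.04
Dxr2-055,Dxr2,MDAMB231,40,0.05
Dxr2-055,Dxr2,H226,40,0.10
Dxr2-055,Dxr2,A549,40,0.96
Dxr2-055,Dxr2,PC3-M,40,0.00
Dxr2-055,Dxr2,LNCaP,40,0.40
Dxr2-069,Dxr2,HT116,40,0.93
Dxr2-069,Dxr2,HT29,40,0.01
Dxr2-069,Dxr2,MCF-7,40,0.03
Dxr2-069,Dxr2,MDAMB231,40,0.59
Dxr2-069,Dxr2,H226,40,0.03
Dxr2-069,Dxr2,A549,40,0.15
Dxr2-069,Dxr2,PC3-M,40,0.00
Dxr2-069,Dxr2,LNCaP,40,-
FolC2-001,FolC2,HT116,40,0.60
FolC2-001,FolC2,HT29,40,0.79
FolC2-001,FolC2,MCF-7,40,0.43
FolC2-001,FolC2,MDAMB231,40,0.28
FolC2-001,FolC2,H226,40,0.00
FolC2-001,FolC2,A549,40,0.53
FolC2-001,FolC2,PC3-M,40,0.41
FolC2-001,FolC2,LNCaP,40,0.34
FolC2-005,FolC2,HT116,40,0.70
FolC2-005,FolC2,HT29,40,0.06
FolC2-005,FolC2,MCF-7,40,0.33
FolC2-005,FolC2,MDAMB231,40,0.78
FolC2-005,FolC2,H226,40,0.11
FolC2-005,FolC2,A549,40,0.69
FolC2-005,FolC2,PC3-M,40,0.00
FolC2-005,FolC2,LNCaP,40,0.28
FolC2-044,FolC2,HT116,40,0.03
FolC2-044,FolC2,HT29,40,0.00
FolC2-044,FolC2,MCF-7,40,0.01
FolC2-044,FolC2,MDAMB231,40,0.16
FolC2-044,FolC2,H226,40,0.00
FolC2-044,FolC2,A549,40,0.15
FolC2-044,FolC2,PC3-M,40,0.00
FolC2-044,FolC2,LNCaP,40,-
FolC1-042,FolC1,HT116,40,0.51
FolC1-042,FolC1,HT29,40,0.10
FolC1-042,FolC1,MCF-7,40,0.64
FolC1-042,FolC1,MDAMB231,40,0.65
FolC1-042,FolC1,H226,40,0.01
FolC1-042,FolC1,A549,40,0.96
FolC1-042,FolC1,PC3-M,40,0.18
FolC1-042,FolC1,LNCaP,40,-
FolC1-020,FolC1,HT116,40,0.23
FolC1-020,FolC1,HT29,40,0.12
FolC1-020,FolC1,MCF-7,40,0.01
FolC1-020,FolC1,MDAMB231,40,0.65
FolC1-020,FolC1,H226,40,0.26
FolC1-020,FolC1,A549,40,0.89
FolC1-020,FolC1,PC3-M,40,0.13
FolC1-020,FolC1,LNCaP,40,-
Dxr1-021,Dxr1,HT116,40,0.95
Dxr1-021,Dxr1,HT29,40,0.59
Dxr1-021,Dxr1,MCF-7,40,0.81
Dxr1-021,Dxr1,MDAMB231,40,0.62
Dxr1-021,Dxr1,H226,40,1.26
Dxr1-021,Dxr1,A549,40,0.72
Dxr1-021,Dxr1,PC3-M,40,0.38
Dxr1-021,Dxr1,LNCaP,40,-
TYLT-072,TYLT,HT116,40,1.18
TYLT-072,TYLT,HT29,40,2.05
TYLT-072,TYLT,MCF-7,40,0.98
TYLT-072,TYLT,MDAMB231,40,0.97
TYLT-072,TYLT,H226,40,0.14
TYLT-072,TYLT,A549,40,1.17
TYLT-072,TYLT,PC3-M,40,0.99
TYLT-072,TYLT,LNCaP,40,-
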
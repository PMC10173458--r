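system,chains,chol_percent,T_K,mu_m_mPas,excluded,set
DMPC,"14:0,14:0",0,333,11.5,FALSE,AA-1
DRPC,"14:1,14:1",0,333,9.8,FALSE,AA-1
DPPC,"16:0,16:0",0,333,15.1,FALSE,AA-1
PYPC,"16:0,16:1",0,333,12.8,FALSE,AA-1
DYPC,"16:1,16:1",0,333,11.1,FALSE,AA-1
DSPC,"18:0,18:0",0,333,NA,TRUE,AA-1
SOPC,"18:0,18:1",0,333,15.6,FALSE,AA-1
SLiPC,"18:0,18:2",0,333,13.7,FALSE,AA-1
DOPC,"18:1,18:1",0,333,16.8,FALSE,AA-1
DLiPC,"18:2,18:2",0,333,11.0,FALSE,AA-1
DOPC^11%,"18:1,18:1",11,333,17.0,FALSE,AA-2
DOPC^20%,"18:1,18:1",20,333,15.6,FALSE,AA-2
DOPC^29%,"18:1,18:1",29,333,18.0,FALSE,AA-2
DOPC^38%,"18:1,18:1",38,333,22.0,FALSE,AA-2
DOPC^47%,"18:1,18:1",47,333,38.7,FALSE,AA-2
POPC,"16:0,18:1",0,298,50.7,FALSE,AA-3
POPC^11%,"16:0,18:1",11,298,54.4,FALSE,AA-3
POPC^20%,"16:0,18:1",20,298,71.6,FALSE,AA-3
POPC^29%,"16:0,18:1",29,298,83.3,FALSE,AA-3
POPC^38%,"16:0,18:1",38,298,129.3,FALSE,AA-3
POPC^47%,"16:0,18:1",47,298,255.4,FALSE,AA-3
DOPC^293K,"18:1,18:1",0,293,65.4,FALSE,AA-4
DOPC^303K,"18:1,18:1",0,303,38.4,FALSE,AA-4
DOPC^313K,"18:1,18:1",0,313,28.0,FALSE,AA-4
DOPC^323K,"18:1,18:1",0,323,16.7,FALSE,AA-4
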
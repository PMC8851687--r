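abbreviation,name,cid
BBP,benzyl butyl phthalate,2347
BPDP,tert-butylphenyl diphenyl phosphate,117291
DBP,dibutyl phthalate,3026
DEHP,bis(2-ethylhexyl) phthalate,8343
DINP,di-iso-nonyl phthalate,590836
DPP,diphenyl phosphate,17167
EHDP,2-ethylhexyl diphenyl phosphate,15168
TBEP,tris(2-butoxyethyl) phosphate,6540
TOCP,tri-o-cresyl phosphate,6527
TPP,triphenyl phosphate,8289
allethrin,allethrin,11442
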
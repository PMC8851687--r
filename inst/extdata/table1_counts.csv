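sample,product,n_features,n_ms2,n_id_ge_40,pct_of_ms2,mdc_hits
HDPE 1,refillable drinking bottle,779,203,38,18.7,TPP
HDPE 2,yogurt drinking bottle,107,34,7,20.6,
HDPE 3,bin liner,614,153,30,19.6,TPP
HDPE 4,shower gel bottle,164,50,16,32.0,EHDP
LDPE 1,lemon juice bottle,241,66,20,30.3,EHDP
LDPE 2,plastic wrap,1833,543,98,18.0,TPP
LDPE 3,freezer bag,1603,416,62,14.9,TPP
LDPE 4,hair conditioner bottle,1702,544,89,16.4,"allethrin, TPP"
PS 1,yogurt cup,447,96,12,12.5,TPP
PS 2,fruit tray,1122,293,44,15.0,"DPP, TPP"
PS 3,vegetable tray,308,63,11,17.5,
PS 4,plastic cup,119,30,7,23.3,
PP 1,refillable drinking bottle,1365,396,87,22.0,TPP
PP 2,yogurt cup,1870,549,93,16.9,TPP
PP 3,gummy candy packaging,3159,910,117,12.9,TPP
PP 4,handkerchief packaging,1798,519,85,16.4,TPP
PP 5,shampoo bottle,268,101,29,28.7,
PET 1,soft drink bottle,148,55,18,32.7,
PET 2,yogurt cup,179,51,12,23.5,
PET 3,oven bag,647,159,30,18.9,
PET 4,vegetable tray,695,182,20,11.0,
PET 5,shampoo bottle,375,89,11,12.4,
PVC 1,plastic wrap,3655,1374,118,8.6,
PVC 2,place mat,2426,819,145,17.7,"DPP, TPP"
PVC 3,pond liner,1270,450,91,20.2,"DINP, TPP"
PVC 4,floor covering,2361,868,145,16.7,"BBP, BPDP, DBP, DEHP, DINP, DPP, EHDP, TBEP, TOCP, TPP"
PUR 1,scouring pad,5619,1773,216,12.2,"EHDP, TPP"
PUR 2,kids bath sponge,4521,1182,151,12.8,
PUR 3,acoustic foam,6242,2117,224,10.6,"EHDP, TPP"
PUR 4,shower slippers,1035,300,78,26.0,"EHDP, TPP"
PLA 1,yogurt cup,2421,772,52,6.7,TPP
PLA 2,vegetable tray,1983,672,40,6.0,
PLA 3,coffee cup lid,NA,NA,NA,NA,
PLA 4,coffee cup lid,2575,857,73,8.5,
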
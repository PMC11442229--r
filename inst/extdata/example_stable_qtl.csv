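trait,population,study,model,method,linkage_group,position,lod,marker_r2,lo,hi,effect_maternal,effect_paternal,effect_interaction
Tacy,CNJ02,upright2024,2011+2012+2013+all years,scanone+stepwiseqtl,3,55.8,NA,0.279,52.9,58.6,-1.70,-11.0,0.48
UBM,CNJ02,upright2024,2012+2013+all years,stepwiseqtl,11,30.8,NA,0.209,30.3,31.2,-0.06,-0.34,0.06
PFR,CNJ02,upright2024,2011+2012+all years,scanone+stepwiseqtl,11,30.8,NA,0.204,30.3,31.2,-10.0,-9.90,2.50
UTBM,CNJ02,upright2024,2011+2012+2013,scanone+stepwiseqtl,11,29.8,NA,0.180,28.4,31.2,0.08,-0.29,0.05
UMFM,CNJ02,upright2024,2012+2013+all years,scanone+stepwiseqtl,11,38.1,NA,0.172,37.5,38.7,-0.11,-0.30,0.08
SFY,CNJ02,upright2024,2011+2012+2013+all years,scanone+stepwiseqtl,12,40.4,NA,0.160,38.1,42.6,10.0,46.0,-1.10
UKLvW,CNJ02,upright2024,2011+2012+all years,scanone+stepwiseqtl,3,30.7,NA,0.152,28.6,32.8,0.04,0.06,0.02
UKLvW,CNJ02,upright2024,2011+2013+all years,scanone,9,82.7,NA,0.135,81.2,84.2,0.03,0.07,0.0042
UBL,CNJ02,upright2024,2012+2013+all years,scanone+stepwiseqtl,10,53.0,NA,0.129,51.8,54.2,-1.80,1.10,-0.74
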
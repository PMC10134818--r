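strain,genes,yield_nmol_per_mmol,se,n,significant_vs_gfp
ZM4_GFP,GFP,5.6,0.5,4,FALSE
ZM4_IspS,IspS,5.8,2.9,3,FALSE
ZM4_DXS2_IspS,DXS2;IspS,33.3,8.6,5,TRUE
ZM4_DXS2_IspS_IDI,DXS2;IspS;IDI,16.3,3.7,8,FALSE
ZM4_DXS2_IspG_IspH_IspS,DXS2;IspG;IspH;IspS,18.1,4.0,5,FALSE
ZM4_DXS2_IspG_IspH_IspS_IDI,DXS2;IspG;IspH;IspS;IDI,20.1,5.9,5,TRUE
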
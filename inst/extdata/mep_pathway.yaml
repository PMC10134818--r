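# Default pathway definition: ED glycolysis end + MEP pathway of Z. mobilis,
# with the heterologous steps (IspS) used in overexpression work.
# Formulas are Hill notation; only carbon is used for balance checks.
metabolites:
  - {id: G6P,  name: Glucose 6-phosphate,                formula: C6H13O9P,  category: ED_glycolysis}
  - {id: 6PG,  name: 6-Phosphogluconate,                 formula: C6H13O10P, category: ED_glycolysis}
  - {id: KDPG, name: 2-Keto-3-deoxy-6-phosphogluconate,  formula: C6H11O9P,  category: ED_glycolysis}
  - {id: GAP,  name: Glyceraldehyde 3-phosphate,         formula: C3H7O6P,   category: ED_glycolysis}
  - {id: PYR,  name: Pyruvate,                           formula: C3H4O3,    category: ED_glycolysis}
  - {id: 3PG,  name: 3-Phosphoglycerate,                 formula: C3H7O7P,   category: ED_glycolysis}
  - {id: PEP,  name: Phosphoenolpyruvate,                formula: C3H5O6P,   category: ED_glycolysis}
  - {id: DXP,  name: 1-Deoxy-D-xylulose 5-phosphate,     formula: C5H11O7P,  category: MEP}
  - {id: MEP,  name: 2-C-methyl-D-erythritol 4-phosphate, formula: C5H13O7P, category: MEP}
  - {id: CDP-ME,  name: 4-Diphosphocytidyl-2-C-methyl-D-erythritol, formula: C14H25N3O14P2, category: MEP}
  - {id: CDP-MEP, name: 4-Diphosphocytidyl-2-C-methyl-D-erythritol 2-phosphate, formula: C14H26N3O17P3, category: MEP}
  - {id: MEcDP,   name: 2-C-methyl-D-erythritol 2,4-cyclodiphosphate, formula: C5H12O9P2, category: MEP}
  - {id: HMBDP,   name: 4-Hydroxy-3-methylbut-2-enyl diphosphate, formula: C5H12O8P2, category: MEP}
  - {id: IDP,     name: Isopentenyl diphosphate,         formula: C5H12O7P2, category: MEP,
     measured_as_pool_with: DMADP}
  - {id: DMADP,   name: Dimethylallyl diphosphate,       formula: C5H12O7P2, category: MEP,
     measured_as_pool_with: IDP}
  - {id: IDP/DMADP, name: IDP + DMADP (combined isomer pool), formula: C5H12O7P2, category: MEP}
  - {id: GPP,  name: Geranyl pyrophosphate,              formula: C10H20O7P2, category: downstream_isoprenoid}
  - {id: FPP,  name: Farnesyl pyrophosphate,             formula: C15H28O7P2, category: downstream_isoprenoid}
  - {id: ISOPRENE, name: Isoprene,                       formula: C5H8,      category: downstream_isoprenoid}
  - {id: ATP,  name: Adenosine triphosphate,             formula: C10H16N5O13P3, category: NTP}
  - {id: GTP,  name: Guanosine triphosphate,             formula: C10H16N5O14P3, category: NTP}
  - {id: UTP,  name: Uridine triphosphate,               formula: C9H15N2O15P3,  category: NTP}
  - {id: CTP,  name: Cytidine triphosphate,              formula: C9H16N3O14P3,  category: NTP}
  - {id: ADP,  name: Adenosine diphosphate,              formula: C10H15N5O10P2, category: cofactor}
  - {id: AMP,  name: Adenosine monophosphate,            formula: C10H14N5O7P,   category: cofactor}
  - {id: GDP,  name: Guanosine diphosphate,              formula: C10H15N5O11P2, category: cofactor}
  - {id: GMP,  name: Guanosine monophosphate,            formula: C10H14N5O8P,   category: cofactor}
  - {id: UDP,  name: Uridine diphosphate,                formula: C9H14N2O12P2,  category: cofactor}
  - {id: UMP,  name: Uridine monophosphate,              formula: C9H13N2O9P,    category: cofactor}
  - {id: CMP,  name: Cytidine monophosphate,             formula: C9H14N3O8P,    category: cofactor}
  - {id: "NADH",  name: NAD (reduced),                   formula: C21H29N7O14P2, category: cofactor}
  - {id: "NAD+",  name: NAD (oxidized),                  formula: C21H28N7O14P2, category: cofactor}
  - {id: "NADPH", name: NADP (reduced),                  formula: C21H30N7O17P3, category: cofactor}
  - {id: "NADP+", name: NADP (oxidized),                 formula: C21H29N7O17P3, category: cofactor}
  - {id: PPi,  name: Diphosphate,                        formula: H4O7P2,    category: other}
  - {id: CO2,  name: Carbon dioxide (aqueous),           formula: CO2,       category: other}
  - {id: H2O,  name: Water,                              formula: H2O,       category: other}
reactions:
  # Electron-donor convention: DXR, IspG and IspH written on the NADPH/NADP+
  # couple. IspG carries no standard free energy (formation energy of MEcDP
  # too uncertain); IspF likewise.
  - id: DXS
    stoichiometry: {PYR: -1, GAP: -1, DXP: 1, CO2: 1}
    main_substrate: PYR
    main_product: DXP
  - id: DXR
    stoichiometry: {DXP: -1, NADPH: -1, MEP: 1, "NADP+": 1}
    main_substrate: DXP
    main_product: MEP
  - id: IspD
    stoichiometry: {MEP: -1, CTP: -1, CDP-ME: 1, PPi: 1}
    main_substrate: MEP
    main_product: CDP-ME
  - id: IspE
    stoichiometry: {CDP-ME: -1, ATP: -1, CDP-MEP: 1, ADP: 1}
    main_substrate: CDP-ME
    main_product: CDP-MEP
  - id: IspF
    stoichiometry: {CDP-MEP: -1, MEcDP: 1, CMP: 1}
    main_substrate: CDP-MEP
    main_product: MEcDP
  - id: IspG
    stoichiometry: {MEcDP: -1, NADPH: -1, HMBDP: 1, "NADP+": 1, H2O: 1}
    main_substrate: MEcDP
    main_product: HMBDP
  - id: IspH
    stoichiometry: {HMBDP: -1, NADPH: -1, IDP/DMADP: 1, "NADP+": 1, H2O: 1}
    main_substrate: HMBDP
    main_product: IDP/DMADP
  - id: IspS
    stoichiometry: {IDP/DMADP: -1, ISOPRENE: 1, PPi: 1}
    main_substrate: IDP/DMADP
    main_product: ISOPRENE
pools:
  # The MEP pool is the six absolutely quantified intermediates; CDP-MEP has
  # no purified standard and GPP/FPP are downstream prenyl diphosphates
  # (an alternative membership including them is provided alongside).
  MEP: [DXP, MEP, CDP-ME, MEcDP, HMBDP, IDP/DMADP]
  MEP_with_prenyl: [DXP, MEP, CDP-ME, MEcDP, HMBDP, IDP/DMADP, GPP, FPP]
  ED_glycolysis: [G6P, 6PG, KDPG, GAP, PYR, 3PG, PEP]
  NTP: [ATP, GTP, UTP, CTP]
  cofactor: ["NADH", "NAD+", "NADPH", "NADP+", ADP, AMP, GDP, GMP, UDP, UMP, CMP]
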
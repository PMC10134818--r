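# Generator scenarios. Fold values marked "reported" encode the study's
# printed strain responses; unmarked values fill in metabolites for which no
# figure value is printed and were chosen once as realistic trajectory
# shapes (monotone rise to a peak, partial relaxation).
single_timepoint:
  GFP:
    description: GFP control; null scenario, all folds 1.
    fold: {}
  DXS2:
    description: DXP synthase overexpression at mid-log (vs GFP control).
    fold:
      DXP: 9.3          # reported
      MEP: 5.0
      CDP-ME: 9.1       # reported
      CDP-MEP: 6.0
      MEcDP: 102.0      # reported
      HMBDP: 5.5        # reported
      IDP/DMADP: 2.5    # reported
  DXR:
    fold: {DXP: 0.46}   # reported
  IspDF:
    fold: {MEP: 3.8, CDP-ME: 78.0}  # reported
  IspE:
    fold: {CDP-ME: 0.19}            # reported
  IspG:
    fold: {MEcDP: 0.24, HMBDP: 2.2, IDP/DMADP: 1.9}  # reported
  IspH:
    fold: {HMBDP: 0.64, IDP/DMADP: 1.8}              # reported
timecourse:
  # Knots are [minutes, fold]; interpolation is piecewise-linear on log(fold).
  GFP:
    description: null time course, everything flat at fold 1.
    trajectory: {}
  DXS2:
    trajectory:
      DXP:       [[0, 1], [7.5, 4], [15, 12], [30, 32], [45, 32], [60, 20], [120, 9.3]]   # peak reported
      MEP:       [[0, 1], [7.5, 3], [15, 9],  [30, 23], [45, 23], [60, 14], [120, 5]]     # peak reported
      CDP-ME:    [[0, 1], [7.5, 3], [15, 8],  [30, 21], [45, 21], [60, 14], [120, 9.1]]   # peak reported
      CDP-MEP:   [[0, 1], [7.5, 2], [15, 5],  [30, 11], [45, 11], [60, 8],  [120, 6]]     # peak reported
      MEcDP:     [[0, 1], [7.5, 4], [15, 8],  [30, 18], [45, 30], [60, 45], [120, 69]]    # 120-min value reported
      HMBDP:     [[0, 1], [7.5, 1.4], [15, 1.8], [30, 2.6], [45, 3.1], [60, 3.5], [120, 3.8]]
      IDP/DMADP: [[0, 1], [7.5, 1.2], [15, 1.4], [30, 1.7], [45, 1.9], [60, 2.1], [120, 2.5]]
  DXS2_IspG:
    trajectory:
      DXP:       [[0, 1], [7.5, 3], [15, 6],  [30, 8],   [45, 7],   [60, 6],   [120, 4]]
      MEP:       [[0, 1], [7.5, 2], [15, 4],  [30, 6],   [45, 6],   [60, 5],   [120, 3]]
      CDP-ME:    [[0, 1], [7.5, 2], [15, 4],  [30, 6],   [45, 6],   [60, 5],   [120, 3]]
      CDP-MEP:   [[0, 1], [7.5, 1.5], [15, 2.5], [30, 4], [45, 3.5], [60, 3],  [120, 2]]
      MEcDP:     [[0, 1], [7.5, 1.5], [15, 2],  [30, 2.5], [45, 2.2], [60, 2], [120, 1.5]]
      HMBDP:     [[0, 1], [7.5, 5], [15, 15], [30, 60],  [45, 110], [60, 140], [120, 90]]  # 60-min value reported
      IDP/DMADP: [[0, 1], [7.5, 3], [15, 9],  [30, 28],  [45, 20],  [60, 15],  [120, 8]]   # 30-min value reported
      GPP:       [[0, 1], [7.5, 3], [15, 10], [30, 33],  [45, 25],  [60, 18],  [120, 10]]  # 30-min value reported
  DXS2_IspG_IspH:
    trajectory:
      DXP:       [[0, 1], [7.5, 2], [15, 4],  [30, 6],  [45, 5],  [60, 4],  [120, 3]]
      MEP:       [[0, 1], [7.5, 2], [15, 3],  [30, 4],  [45, 4],  [60, 3],  [120, 2]]
      CDP-ME:    [[0, 1], [7.5, 2], [15, 3],  [30, 4],  [45, 4],  [60, 3],  [120, 2]]
      CDP-MEP:   [[0, 1], [7.5, 1.5], [15, 2], [30, 3], [45, 3],  [60, 2.5], [120, 2]]
      MEcDP:     [[0, 1], [7.5, 3], [15, 6],  [30, 12], [45, 25], [60, 18], [120, 8]]   # 45-min value reported
      HMBDP:     [[0, 1], [7.5, 1.5], [15, 2.5], [30, 3.3], [45, 3], [60, 2.5], [120, 2]]  # 30-min value reported
      IDP/DMADP: [[0, 1], [7.5, 1.5], [15, 2], [30, 3],  [45, 3],  [60, 2.5], [120, 2]]
physiology:
  # Isoprene yields (nmol isoprene per mmol glucose) from the production
  # table; growth parameters chosen as realistic for anaerobic minimal-media
  # growth of Z. mobilis.
  yields:
    ZM4_GFP:                      {yield: 5.6,  se: 0.5, n: 4}
    ZM4_IspS:                     {yield: 5.8,  se: 2.9, n: 3}
    ZM4_DXS2_IspS:                {yield: 33.3, se: 8.6, n: 5}
    ZM4_DXS2_IspS_IDI:            {yield: 16.3, se: 3.7, n: 8}
    ZM4_DXS2_IspG_IspH_IspS:      {yield: 18.1, se: 4.0, n: 5}
    ZM4_DXS2_IspG_IspH_IspS_IDI:  {yield: 20.1, se: 5.9, n: 5}
  growth: {od0: 0.05, mu_per_h: 0.30, od_cap: 2.0}
  glucose: {initial_mM: 111.0, q_mmol_gdcw_h: 30.0}
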
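# Synthetic stand-in standard transformed reaction energies (kJ/mol) for the
# MEP pathway at pH 6, ionic strength 0.25 M, pMg 3, 30 C. These are NOT
# component-contribution estimates: they are plausible values chosen once for
# testing and for exercising the in vivo deltaG machinery. Regenerate with a
# component-contribution tool at the stated conditions to analyse real data.
# IspF and IspG carry no value (formation energy of MEcDP too uncertain).
reaction,dg0_prime_kj_mol,se_kj_mol
DXS,-50.0,5.0
DXR,-40.0,5.0
IspD,-8.3,4.0
IspE,-12.0,6.0
IspH,-130.0,8.0
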
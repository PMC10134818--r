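metabolite,abbreviation,molarity_M,source
Glucose 6-phosphate,G6P,5.00E-03,literature
6-Phosphogluconate,6PG,2.09E-03,literature
2-Keto-3-deoxy-6-phosphogluconate,KDPG,6.39E-03,literature
Glyceraldehyde 3-phosphate,GAP,1.00E-03,this_study
Pyruvate,PYR,6.35E-03,this_study
3-Phosphoglycerate,3PG,3.85E-03,literature
Phosphoenolpyruvate,PEP,4.02E-05,literature
1-Deoxy-d-xylulose 5-phosphate,DXP,1.68E-04,this_study
2-C-methyl-d-erythritol 4-phosphate,MEP,1.40E-05,this_study
4-Diphosphocytidyl-2-C-methyl-d-erythritol,CDP-ME,3.60E-05,this_study
"2-C-methyl-d-erythritol 2,4-cyclodiphosphate",MEcDP,1.25E-04,this_study
4-Hydroxy-3-methylbut-2-enyl-diphosphate,HMBDP,7.40E-06,this_study
Isopentenyl diphosphate-dimethylallyl diphosphate,IDP/DMADP,7.09E-06,this_study
Geranyl pyrophosphate,GPP,3.28E-06,this_study
Farnesyl pyrophosphate,FPP,2.56E-05,this_study
Adenosine triphosphate,ATP,2.81E-03,this_study
Adenosine diphosphate,ADP,1.27E-03,this_study
Adenosine monophosphate,AMP,8.89E-05,literature
Guanosine triphosphate,GTP,1.72E-03,literature
Guanosine diphosphate,GDP,4.23E-04,literature
Guanosine monophosphate,GMP,5.16E-05,literature
Uridine triphosphate,UTP,1.81E-03,literature
Uridine diphosphate,UDP,4.47E-04,literature
Uridine monophosphate,UMP,8.94E-05,literature
Cytidine triphosphate,CTP,1.12E-03,this_study
Cytidine monophosphate,CMP,3.42E-05,this_study
Nicotinamide adenine dinucleotide (reduced),NADH,4.13E-04,literature
Nicotinamide adenine dinucleotide (oxidized),NAD+,2.21E-03,literature
Nicotinamide adenine dinucleotide phosphate (reduced),NADPH,5.51E-04,literature
Nicotinamide adenine dinucleotide phosphate (oxidized),NADP+,3.00E-04,literature
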
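# Candidate-retention counts for 19 standards with Level-1 assignments in
# indoor/outdoor air samples: total candidates detected per feature and the
# number retained by each annotation filter, plus flags recording whether the
# correct candidate survived combined Level-2 filtering and whether its
# molecular ion was observed.
compound,total_detected,level3_all,level2_all,level2_ri,level2_rsi,level2_rhrmf,molecular_ion,correct_level2,correct_molecular_ion
Benz[a]anthracene,25,14,3,5,18,16,11,Yes,Yes
Chrysene,39,19,3,4,33,24,11,Yes,Yes
Fluoranthene,54,28,9,12,34,43,6,Yes,Yes
Fluorene,33,29,7,9,32,29,7,Yes,Yes
Acenaphthylene,33,23,7,12,33,23,5,Yes,Yes
Naphthalene,40,32,8,11,40,32,9,Yes,Yes
Phenanthrene,38,38,7,7,38,38,13,Yes,Yes
Pyrene,53,23,7,7,36,34,6,Yes,Yes
2-Chloronaphthalene,27,13,2,6,27,13,3,Yes,Yes
Dibenzofuran,49,29,5,16,48,29,12,Yes,Yes
Hexachlorobenzene,32,9,6,12,31,9,5,Yes,Yes
Hexachlorobutadiene,32,2,1,2,26,2,1,Yes,Yes
Tris(1-chloro-2-propyl) phosphate,20,5,3,7,17,7,0,No,No
"4,4'-Dibromooctafluorobiphenyl",27,1,1,2,27,1,1,Yes,Yes
Isophorone,49,46,19,19,49,46,8,Yes,Yes
N-Nitrosodiphenylamine,46,35,4,4,46,35,23,No,No
Butylbenzyl phthalate,21,7,4,7,18,7,3,Yes,No
Diethyl phthalate,28,18,4,6,27,18,0,Yes,No
Di-n-octyl phthalate,53,45,9,10,52,45,1,No,No
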
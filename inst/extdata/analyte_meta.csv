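analyte,class,parent,rfd_mg_per_kg_day,rpf,lod_ng_per_g
benzo[a]anthracene,cpah7,,,0.1,0.40878
chrysene,cpah7,,,0.001,0.40878
benzo[b]fluoranthene,cpah7,,,0.1,0.40878
benzo[k]fluoranthene,cpah7,,,0.01,0.40878
benzo[a]pyrene,cpah7,,,1,0.40878
"indeno[1,2,3-c,d]pyrene",cpah7,,,0.1,0.40878
"dibenzo[a,h]anthracene",cpah7,,,1,0.40878
naphthalene,unsubstituted,,0.02,,1.2428
biphenyl,unsubstituted,,,,1.2428
acenaphthylene,unsubstituted,,,,1.2428
acenaphthene,unsubstituted,,,,1.2428
fluorene,unsubstituted,,0.04,,1.2428
dibenzofuran,unsubstituted,,,,1.2428
phenanthrene,unsubstituted,,0.3,,1.2428
anthracene,unsubstituted,,0.3,,1.2428
fluoranthene,unsubstituted,,0.04,,1.2428
pyrene,unsubstituted,,0.03,,1.2428
benzo[e]pyrene,unsubstituted,,,,1.2428
perylene,unsubstituted,,,,1.2428
"benzo[g,h,i]perylene",unsubstituted,,,,1.2428
dibenzothiophene,unsubstituted,,,,1.2428
carbazole,unsubstituted,,,,1.2428
naphthobenzothiophene,unsubstituted,,,,1.2428
retene,unsubstituted,,,,1.2428
benzo[a]fluorene,unsubstituted,,,,1.2428
benzo[b]fluorene,unsubstituted,,,,1.2428
benzo[j]fluoranthene,unsubstituted,,,,1.2428
triphenylene,unsubstituted,,,,1.2428
coronene,unsubstituted,,,,1.2428
picene,unsubstituted,,,,1.2428
benzo[c]phenanthrene,unsubstituted,,,,1.2428
"cyclopenta[c,d]pyrene",unsubstituted,,,,1.2428
anthanthrene,unsubstituted,,,,1.2428
"dibenzo[a,e]pyrene",unsubstituted,,,,1.2428
"dibenzo[a,h]pyrene",unsubstituted,,,,1.2428
"dibenzo[a,i]pyrene",unsubstituted,,,,1.2428
"dibenzo[a,l]pyrene",unsubstituted,,,,1.2428
"benzo[g,h,i]fluoranthene",unsubstituted,,,,1.2428
acephenanthrylene,unsubstituted,,,,1.2428
"dibenz[a,c]anthracene",unsubstituted,,,,1.2428
2-methylnaphthalene,alkylated,naphthalene,,,0.5116
1-methylnaphthalene,alkylated,naphthalene,,,0.5116
C2-naphthalenes,alkylated,naphthalene,,,0.5116
C3-naphthalenes,alkylated,naphthalene,,,0.5116
C4-naphthalenes,alkylated,naphthalene,,,0.5116
"2,6-dimethylnaphthalene",alkylated,naphthalene,,,0.5116
"1,6,7-trimethylnaphthalene",alkylated,naphthalene,,,0.5116
1-methylphenanthrene,alkylated,phenanthrene,,,0.5116
2-methylphenanthrene,alkylated,phenanthrene,,,0.5116
3-methylphenanthrene,alkylated,phenanthrene,,,0.5116
9-methylphenanthrene,alkylated,phenanthrene,,,0.5116
C1-phenanthrenes,alkylated,phenanthrene,,,0.5116
C2-phenanthrenes,alkylated,phenanthrene,,,0.5116
C3-phenanthrenes,alkylated,phenanthrene,,,0.5116
C4-phenanthrenes,alkylated,phenanthrene,,,0.5116
2-methylanthracene,alkylated,anthracene,,,0.5116
9-methylanthracene,alkylated,anthracene,,,0.5116
1-methylfluorene,alkylated,fluorene,,,0.5116
C1-fluorenes,alkylated,fluorene,,,0.5116
C2-fluorenes,alkylated,fluorene,,,0.5116
C3-fluorenes,alkylated,fluorene,,,0.5116
4-methyldibenzothiophene,alkylated,dibenzothiophene,,,0.5116
C1-dibenzothiophenes,alkylated,dibenzothiophene,,,0.5116
C2-dibenzothiophenes,alkylated,dibenzothiophene,,,0.5116
C3-dibenzothiophenes,alkylated,dibenzothiophene,,,0.5116
C4-dibenzothiophenes,alkylated,dibenzothiophene,,,0.5116
5-methylchrysene,alkylated,chrysene,,,0.5116
6-methylchrysene,alkylated,chrysene,,,0.5116
C1-chrysenes,alkylated,chrysene,,,0.5116
C2-chrysenes,alkylated,chrysene,,,0.5116
C3-chrysenes,alkylated,chrysene,,,0.5116
C4-chrysenes,alkylated,chrysene,,,0.5116
1-methylpyrene,alkylated,pyrene,,,0.5116
C1-pyrenes,alkylated,pyrene,,,0.5116
C2-pyrenes,alkylated,pyrene,,,0.5116
C3-pyrenes,alkylated,pyrene,,,0.5116
C4-pyrenes,alkylated,pyrene,,,0.5116
C1-fluoranthenes,alkylated,fluoranthene,,,0.5116
C2-fluoranthenes,alkylated,fluoranthene,,,0.5116
C1-naphthobenzothiophenes,alkylated,naphthobenzothiophene,,,0.5116
7-methylbenzo[a]pyrene,alkylated,benzo[a]pyrene,,,0.5116
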
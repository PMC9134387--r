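kind,name,smiles,rings,lipo,polar
scaffold,benzene,c1cc{A}ccc1{T},1,1.7,0
scaffold,pyridine,c1cc{A}cnc1{T},1,0.8,12.9
scaffold,cyclohexane,C1CC{A}CCC1{T},1,2.3,0
scaffold,thiophene,c1cc{A}sc1{T},1,1.6,28.2
scaffold,furan,c1cc{A}oc1{T},1,1.0,13.1
scaffold,naphthalene,c1ccc2cc{A}ccc2c1{T},2,2.8,0
scaffold,quinoline,c1ccc2nc{A}ccc2c1{T},2,1.9,12.9
scaffold,tetralin,C1CCc2cc{A}ccc2C1{T},2,3.0,0
scaffold,biphenyl,c1ccc(cc1)c1cc{A}ccc1{T},2,3.3,0
scaffold,anthracene,c1ccc2cc3cc{A}ccc3cc2c1{T},3,3.9,0
scaffold,benzoquinoline,c1ccc2cc3cc{A}ccc3nc2c1{T},3,3.0,12.9
scaffold,terphenyl,c1ccc(cc1)c1ccc(cc1)c1cc{A}ccc1{T},3,4.9,0
substituent,hydrogen,,0,0,0
substituent,methyl,C,0,0.5,0
substituent,ethyl,CC,0,1.0,0
substituent,propyl,CCC,0,1.5,0
substituent,isopropyl,C(C)C,0,1.4,0
substituent,fluoro,F,0,0.2,0
substituent,chloro,Cl,0,0.7,0
substituent,bromo,Br,0,0.9,0
substituent,trifluoromethyl,C(F)(F)F,0,1.0,0
substituent,hydroxy,O,0,-0.7,20.2
substituent,methoxy,OC,0,-0.1,9.2
substituent,amino,N,0,-1.2,26.0
substituent,methylamino,NC,0,-0.7,12.0
substituent,dimethylamino,N(C)C,0,-0.3,3.2
substituent,carboxyl,C(=O)O,0,-0.3,37.3
substituent,amide,C(=O)N,0,-1.0,43.1
substituent,nitrile,C#N,0,-0.4,23.8
substituent,acetyl,C(C)=O,0,-0.2,17.1
substituent,methylsulfanyl,SC,0,0.6,25.3
substituent,aminoethyl,CCN,0,-0.9,26.0
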
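compound,formula,smiles
Gallic acid,C7H6O5,OC(=O)c1cc(O)c(O)c(O)c1
Gentisic acid,C7H6O4,OC(=O)c1cc(O)ccc1O
Protocatechuic acid,C7H6O4,OC(=O)c1ccc(O)c(O)c1
Salicylic acid,C7H6O3,OC(=O)c1ccccc1O
Syringic acid,C9H10O5,COc1cc(C(O)=O)cc(OC)c1O
Vanillic acid,C8H8O4,COc1cc(C(O)=O)ccc1O
"2,4-Dihydroxybenzoic acid",C7H6O4,OC(=O)c1ccc(O)cc1O
3-Methoxybenzoic acid,C8H8O3,COc1cccc(C(O)=O)c1
4-Hydroxybenzoic acid,C7H6O3,OC(=O)c1ccc(O)cc1
Caffeic acid,C9H8O4,OC(=O)/C=C/c1ccc(O)c(O)c1
Chlorogenic acid,C16H18O9,O[C@@H]1C[C@](O)(C[C@H](OC(=O)/C=C/c2ccc(O)c(O)c2)[C@@H]1O)C(O)=O
Ferulic acid,C10H10O4,COc1cc(/C=C/C(O)=O)ccc1O
m-Coumaric acid,C9H8O3,OC(=O)/C=C/c1cccc(O)c1
o-Coumaric acid,C9H8O3,OC(=O)/C=C/c1ccccc1O
p-Coumaric acid,C9H8O3,OC(=O)/C=C/c1ccc(O)cc1
Sinapic acid,C11H12O5,COc1cc(/C=C/C(O)=O)cc(OC)c1O
trans-Cinnamic acid,C9H8O2,OC(=O)/C=C/c1ccccc1
Dihydrocaffeic acid,C9H10O4,OC(=O)CCc1ccc(O)c(O)c1
Homovanillic acid,C9H10O4,COc1cc(CC(O)=O)ccc1O
DOPAC,C8H8O4,OC(=O)Cc1ccc(O)c(O)c1
4-Hydroxyphenylacetic acid,C8H8O3,OC(=O)Cc1ccc(O)cc1
Ellagic acid,C14H6O8,C1=C2C3=C(C(=C1O)O)OC(=O)C4=CC(=C(C(=C43)OC2=O)O)O
Vanillin,C8H8O3,COc1cc(C=O)ccc1O
Tyrosol,C8H10O2,OCCc1ccc(O)cc1
Apigenin,C15H10O5,Oc1ccc(cc1)-c1cc(=O)c2c(O)cc(O)cc2o1
Chrysin,C15H10O4,Oc1cc(O)c2c(c1)oc(-c1ccccc1)cc2=O
Luteolin,C15H10O6,Oc1cc(O)c2c(c1)oc(-c1ccc(O)c(O)c1)cc2=O
Luteolin-7-O-glucoside,C21H20O11,OC[C@H]1O[C@@H](Oc2cc(O)c3c(c2)oc(-c2ccc(O)c(O)c2)cc3=O)[C@H](O)[C@@H](O)[C@@H]1O
Kaempferide,C16H12O6,COc1ccc(cc1)-c1oc2cc(O)cc(O)c2c(=O)c1O
Myricetin,C15H10O8,Oc1cc(O)c2c(c1)oc(-c1cc(O)c(O)c(O)c1)c(O)c2=O
Quercetin,C15H10O7,Oc1cc(O)c2c(c1)oc(-c1ccc(O)c(O)c1)c(O)c2=O
Rutin,C27H30O16,C[C@@H]1O[C@@H](OC[C@H]2O[C@@H](Oc3c(-c4ccc(O)c(O)c4)oc4cc(O)cc(O)c4c3=O)[C@H](O)[C@@H](O)[C@@H]2O)[C@H](O)[C@H](O)[C@H]1O
Hesperidin,C28H34O15,C[C@@H]1O[C@@H](OC[C@H]2O[C@@H](Oc3cc(O)c4c(c3)O[C@@H](CC4=O)c3ccc(OC)c(O)c3)[C@H](O)[C@@H](O)[C@@H]2O)[C@H](O)[C@H](O)[C@H]1O
Isosakuranetin,C16H14O5,COc1ccc(cc1)[C@@H]1CC(=O)c2c(O)cc(O)cc2O1
Naringenin,C15H12O5,Oc1ccc(cc1)[C@@H]1CC(=O)c2c(O)cc(O)cc2O1
(+)-Catechin,C15H14O6,O[C@@H]1Cc2c(O)cc(O)cc2O[C@@H]1c1ccc(O)c(O)c1
(-)-Epicatechin,C15H14O6,O[C@H]1Cc2c(O)cc(O)cc2O[C@@H]1c1ccc(O)c(O)c1
Genistein,C15H10O5,Oc1ccc(cc1)-c1coc2cc(O)cc(O)c2c1=O
(+)-Taxifolin,C15H12O7,O[C@@H]1[C@H](Oc2cc(O)cc(O)c2C1=O)c1ccc(O)c(O)c1
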
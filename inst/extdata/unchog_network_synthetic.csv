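# SYNTHETIC stand-in for the deposited Unchog visitation matrix.
# Constructed to satisfy every published constraint (dimensions, total
# visits, unique links, named species degrees, robber-filter outcome);
# individual cell values are invented.
# pollinet interaction_matrix
species,Metallura theresiae,Metallura tyrianthina,Pterophanes cyanopterus,Heliangelus amethysticollis,Aglaeactis cupripennis,Coeligena violifer,Lafresnaya lafresnayi,Lesbia nuna,Chalcostigma stanleyi,Colibri coruscans,Adelomyia melanogenys,Oreotrochilus estella,Diglossa mystacalis,Diglossa cyanea,Diglossa brunneiventris,Diglossa albilatera,Conirostrum cinereum
Brachyotum lutescens,22,6,0,0,6,0,0,3,3,0,0,0,11,4,2,0,0
Tristerix longebracteatus,18,0,5,0,4,4,2,0,0,0,0,0,8,3,0,0,0
Fuchsia decussata,15,5,0,0,0,4,3,0,0,0,2,0,7,0,0,2,0
Desfontainia spinosa,10,0,2,3,0,3,0,0,0,0,0,0,5,0,0,0,0
Passiflora cumbalensis,8,2,4,0,0,0,0,0,0,0,0,0,4,0,0,0,0
Puya sp.,9,0,4,0,2,0,0,0,0,0,0,3,0,2,0,0,0
Centropogon sp.,0,0,0,0,0,0,0,0,0,0,2,0,0,0,1,0,0
Barnadesia sp.,5,0,0,2,0,0,0,0,0,0,0,0,0,0,0,0,0
Berberis sp.,5,0,0,0,0,0,0,0,2,0,0,0,0,0,0,0,0
Bomarea sp.,4,0,0,0,0,0,0,2,0,0,0,0,0,0,0,0,0
Salvia sp.,3,0,0,0,0,0,0,0,0,2,0,0,0,0,0,0,0
Gaultheria sp.,3,0,0,0,0,0,0,0,0,0,0,0,3,0,0,0,1
Macleania sp.,3,0,0,0,0,0,2,0,0,0,0,0,0,0,0,0,0
Miconia sp.,2,0,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0
Mutisia sp.,2,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
Oreocallis sp.,2,0,0,2,0,0,0,0,0,0,0,0,0,0,0,0,0
Ribes sp.,2,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0
Siphocampylus sp.,2,3,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
Symplocos sp.,2,0,0,0,0,0,0,0,0,0,0,0,2,0,0,0,0
Vaccinium sp.,2,0,0,0,0,0,0,0,0,0,0,0,2,0,0,0,0
Gentianella sp.,2,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
Disterigma sp.,2,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0
Bejaria sp.,1,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0
Lupinus sp.,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
Embothrium sp.,1,0,0,0,0,0,0,0,0,2,0,0,0,0,0,0,0
Solanum sp.,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
Clusia sp.,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
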
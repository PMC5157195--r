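# SYNTHETIC stand-in trait table (species characteristics);
# values are plausible but invented.
species,corolla_lo,corolla_hi,corolla_width,wide_flower
Brachyotum lutescens,10,14,6,FALSE
Tristerix longebracteatus,30,40,4,FALSE
Fuchsia decussata,20,30,6,FALSE
Desfontainia spinosa,35,45,8,FALSE
Passiflora cumbalensis,70,90,10,FALSE
Puya sp.,40,50,25,TRUE
Centropogon sp.,22,30,5,FALSE
Barnadesia sp.,12,18,4,FALSE
Berberis sp.,8,12,3,FALSE
Bomarea sp.,25,35,6,FALSE
Salvia sp.,18,26,5,FALSE
Gaultheria sp.,6,10,3,FALSE
Macleania sp.,14,20,4,FALSE
Miconia sp.,5,9,3,FALSE
Mutisia sp.,15,25,5,FALSE
Oreocallis sp.,28,38,6,FALSE
Ribes sp.,6,10,3,FALSE
Siphocampylus sp.,24,34,5,FALSE
Symplocos sp.,8,12,3,FALSE
Vaccinium sp.,6,10,3,FALSE
Gentianella sp.,12,18,4,FALSE
Disterigma sp.,7,11,3,FALSE
Bejaria sp.,10,16,4,FALSE
Lupinus sp.,12,18,5,FALSE
Embothrium sp.,26,36,6,FALSE
Solanum sp.,10,16,4,FALSE
Clusia sp.,8,14,4,FALSE
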
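# SYNTHETIC stand-in trait table (species characteristics);
# values are plausible but invented.
species,bill_lo,bill_hi,tongue_fraction,legitimacy
Metallura theresiae,14,16,0.333333333333333,legitimate
Metallura tyrianthina,12,14,0.333333333333333,legitimate
Pterophanes cyanopterus,31,35,0.333333333333333,legitimate
Heliangelus amethysticollis,16,18,0.333333333333333,legitimate
Aglaeactis cupripennis,18,20,0.333333333333333,legitimate
Coeligena violifer,28,32,0.333333333333333,legitimate
Lafresnaya lafresnayi,20,24,0.333333333333333,legitimate
Lesbia nuna,13,15,0.333333333333333,legitimate
Chalcostigma stanleyi,10,12,0.333333333333333,legitimate
Colibri coruscans,23,27,0.333333333333333,legitimate
Adelomyia melanogenys,13,15,0.333333333333333,legitimate
Oreotrochilus estella,17,19,0.333333333333333,legitimate
Diglossa mystacalis,11,13,0.333333333333333,robber
Diglossa cyanea,12,14,0.333333333333333,robber
Diglossa brunneiventris,11,13,0.333333333333333,robber
Diglossa albilatera,10,12,0.333333333333333,robber
Conirostrum cinereum,9,11,0.333333333333333,robber
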
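# Illegitimate-visit pair exclusions reported in the study.
plant,bird
Desfontainia spinosa,Heliangelus amethysticollis
Passiflora cumbalensis,Pterophanes cyanopterus
Passiflora cumbalensis,Metallura tyrianthina
Desfontainia spinosa,Metallura theresiae
Fuchsia decussata,Metallura theresiae
Passiflora cumbalensis,Metallura theresiae
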
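# Microbes significantly changed in the human gut under an animal-based
# diet (species and genus ranks), one name per line.
Eubacterium biforme
Microbe MLG480
Actinobacillus porcinus
Alistipes finegoldii
Alistipes putredinis
Bacteroides coprocola
Bacteroides fragilis
Bacteroides salyersiae
Bifidobacterium adolescentis
Bifidobacterium gallicum
Bifidobacterium longum
Bilophila wadsworthia
Blautia producta
Clostridium bolteae
Clostridium orbiscindens
Collinsella aerofaciens
Dialister invisus
Faecalibacterium prausnitzii
Megasphaera elsdenii
Mitsuokella multacida
Parabacteroides johnsonii
Prevotella copri
Raoultella
Roseburia Eubacteriumrectale
Roseburia faecis
Ruminococcus bromii
Ruminococcus callidus
Ruminococcus flavefaciens
Ruminococcus gnavus
Alistipes
Akkermansia
Bacteroides
Bifidobacterium
Blautia
Catenibacterium
Clostridium
Coprococcus
Dialister
Escherichia
Eubacterium
Faecalibacterium
Lachnobacterium
Lachnospira
Odoribacter
Oscillospira
Parabacteroides
Phascolarctobacterium
Roseburia
Prevotella
Ruminococcus
Sutterella
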
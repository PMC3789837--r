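code	name	clade	is_metazoan	well_sequenced
hsa	Homo sapiens	Craniata	true	true
mmu	Mus musculus	Craniata	true	true
rno	Rattus norvegicus	Craniata	true	true
cfa	Canis familiaris	Craniata	true	true
bta	Bos taurus	Craniata	true	true
gga	Gallus gallus	Craniata	true	true
xtr	Xenopus tropicalis	Craniata	true	true
dre	Danio rerio	Craniata	true	true
tni	Tetraodon nigroviridis	Craniata	true	true
tru	Takifugu rubripes	Craniata	true	true
mdo	Monodelphis domestica	Craniata	true	true
cin	Ciona intestinalis	Urochordata	true	true
dme	Drosophila melanogaster	Arthropoda	true	true
dps	Drosophila pseudoobscura	Arthropoda	true	true
aga	Anopheles gambiae	Arthropoda	true	true
aae	Aedes aegypti	Arthropoda	true	true
cqu	Culex quinquefasciatus	Arthropoda	true	true
ame	Apis mellifera	Arthropoda	true	true
nvi	Nasonia vitripennis	Arthropoda	true	true
phu	Pediculus humanus	Arthropoda	true	true
cel	Caenorhabditis elegans	Nematoda	true	true
cbr	Caenorhabditis briggsae	Nematoda	true	true
bma	Brugia malayi	Nematoda	true	true
nve	Nematostella vectensis	Cnidaria	true	true
tad	Trichoplax adhaerens	Placozoa	true	true
sce	Saccharomyces cerevisiae	Fungi	false	true
spo	Schizosaccharomyces pombe	Fungi	false	true
ath	Arabidopsis thaliana	Viridiplantae	false	true
osa	Oryza sativa	Viridiplantae	false	true
ddi	Dictyostelium discoideum	Amoebozoa	false	true
mbr	Monosiga brevicollis	Choanoflagellata	false	true
pfa	Plasmodium falciparum	Alveolata	false	true
tgo	Toxoplasma gondii	Alveolata	false	true
eco	Escherichia coli	Prokaryota	false	true
bsu	Bacillus subtilis	Prokaryota	false	true
nm001	Synthetic non-metazoan 1	Fungi	false	true
nm002	Synthetic non-metazoan 2	Prokaryota	false	true
nm003	Synthetic non-metazoan 3	Viridiplantae	false	true
nm004	Synthetic non-metazoan 4	Prokaryota	false	true
nm005	Synthetic non-metazoan 5	Alveolata	false	false
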
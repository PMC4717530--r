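# Per-species niche-cluster locality counts for the Madagascan Bulbophyllum
# study clade (sects. Bifalcula, Calamaria, Humblotiorchis) plus three
# outgroup species, transcribed from the published table. Digit grouping in
# the printed rows for B. bicoloratum and B. occultum is ambiguous; the
# reading below (3/10/43 and 1/61/86) is the one consistent with the
# published record total (604), the hard-cluster column sums, the stated
# per-species count range (1..148), and the printed Coding column.
species,section,nA,nB,nC
B. capuronii,Bifalcula,0,4,0
B. complanatum,Bifalcula,11,0,0
B. implexum,Bifalcula,12,0,0
B. minutum,Bifalcula,0,12,0
B. sp. nov. A,Bifalcula,0,3,0
B. sp. nov. B,Bifalcula,0,0,1
B. bicoloratum,Calamaria,3,10,43
B. cirrhoglossum,Calamaria,0,4,0
B. elliotii,Calamaria,1,19,0
B. erectum,Calamaria,21,48,0
B. hildebrandtii,Calamaria,17,0,14
B. histrionicum,Calamaria,20,0,0
B. incurvum,Calamaria,0,0,5
B. lecouflei,Calamaria,2,3,0
B. luteobracteatum,Calamaria,0,0,4
B. malawiense,Calamaria,0,0,2
B. obtusatum,Calamaria,1,0,9
B. occultum,Calamaria,1,61,86
B. pervillei,Calamaria,0,18,0
B. pusillum,Calamaria,2,2,35
B. quadrifarium,Calamaria,0,11,1
B. rubrum,Calamaria,9,0,0
B. ruginosum,Calamaria,0,0,3
B. senghasii,Calamaria,1,0,0
B. sp. nov. C,Calamaria,0,7,0
B. sp. nov. D,Calamaria,0,0,1
B. sp. nov. E1,Calamaria,12,0,0
B. sp. nov. E2,Calamaria,1,0,0
B. trifarium,Calamaria,8,0,2
B. humblotii,Humblotiorchis,4,35,6
B. variegatum,Alcistachys,0,12,3
B. cardiobulbum,Inversiflorum,0,0,10
B. horizontale,Kainochilus,0,0,4
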
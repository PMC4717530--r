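# Published niche-state Coding column for the study clade. Used as
# overrides on the majority/one-third rule: the single rule-inconsistent
# species under the adopted count reading is B. erectum (21/48/0 -> rule
# {B}, published AB).
species,states
B. capuronii,B
B. complanatum,A
B. implexum,A
B. minutum,B
B. sp. nov. A,B
B. sp. nov. B,C
B. bicoloratum,C
B. cirrhoglossum,B
B. elliotii,B
B. erectum,A|B
B. hildebrandtii,A|C
B. histrionicum,A
B. incurvum,C
B. lecouflei,A|B
B. luteobracteatum,C
B. malawiense,C
B. obtusatum,C
B. occultum,B|C
B. pervillei,B
B. pusillum,C
B. quadrifarium,B
B. rubrum,A
B. ruginosum,C
B. senghasii,A
B. sp. nov. C,B
B. sp. nov. D,C
B. sp. nov. E1,A
B. sp. nov. E2,A
B. trifarium,A
B. humblotii,B
B. variegatum,B
B. cardiobulbum,C
B. horizontale,C
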
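gene	category	citation
Foxo1	literature_confirmed	reported-target
Foxo3	literature_confirmed	reported-target
Mitf	literature_confirmed	reported-target
Adcy6	literature_confirmed	reported-target
Clic5	literature_confirmed	reported-target
Scarb1	literature_confirmed	reported-target
Nr3c1	literature_confirmed	reported-target
Scn3a	literature_confirmed	reported-target
Spast	literature_confirmed	reported-target
Gpc3	literature_confirmed	reported-target
Insig2	literature_confirmed	reported-target
Irs1	literature_confirmed	reported-target
Slc1a1	literature_confirmed	reported-target
Gpc1	literature_confirmed	reported-target
Alk	literature_confirmed	reported-target
Rad51	literature_confirmed	reported-target
Rev1	literature_confirmed	reported-target
Hbp1	literature_confirmed	reported-target
Reck	literature_confirmed	reported-target
Aqp5	luciferase_confirmed	luciferase-assay
Celsr2	luciferase_confirmed	luciferase-assay
Odf2	luciferase_confirmed	luciferase-assay
Hspa2	upregulated_with_seed_match	mutant-upregulated-seed-match
Pnpla8	upregulated_with_seed_match	mutant-upregulated-seed-match
Sdc2	upregulated_with_seed_match	mutant-upregulated-seed-match
Arf2	upregulated_with_seed_match	mutant-upregulated-seed-match
Casc1	upregulated_with_seed_match	mutant-upregulated-seed-match
Gad2	upregulated_with_seed_match	mutant-upregulated-seed-match
St8sia3	upregulated_with_seed_match	mutant-upregulated-seed-match
Zic2	predicted_and_expressed	predicted-upregulated-P4
Osbpl2	predicted_and_expressed	predicted-stereocilia-expressed
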
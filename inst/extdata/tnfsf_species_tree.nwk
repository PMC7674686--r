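((Eptatretus_burgeri,(Petromyzon_marinus,Lethenteron_camtschaticum)lamprey_ancestor)agnathan_ancestor,((Callorhinchus_milii,Rhincodon_typus)chondrichthyan_ancestor,((Lepisosteus_oculatus,(Danio_rerio,Takifugu_rubripes)teleost_ancestor)actinopterygian_ancestor,(Latimeria_chalumnae,Homo_sapiens)sarcopterygian_ancestor)osteichthyan_ancestor)gnathostome_ancestor)vertebrate_ancestor;
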
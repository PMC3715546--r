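(((Cynopterus_sphinx,(Rousettus_leschenaultii,Eonycteris_spelaea)),(((Rhinolophus_luctus,(Rhinolophus_pearsonii,(Rhinolophus_pusillus,Rhinolophus_sinicus))),(Hipposideros_armiger,Hipposideros_pratti)),(Megaderma_lyra,Megaderma_spasma))),(Emballonura_raffrayana,(((Mormoops_megalophylla,(Pteronotus_davyi,Pteronotus_parnellii)),Artibeus_jamaicensis),(Pipistrellus_abramus,Tadarida_brasiliensis))));
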
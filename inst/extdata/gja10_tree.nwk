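(((Cynopterus_sphinx,((Rousettus_leschenaultii,Rousettus_aegyptiacus),(Eonycteris_spelaea,(Pteropus_giganteus,Dobsonia_viridis)))),(((Rhinolophus_ferrumequinum,(Rhinolophus_pusillus,(Rhinolophus_sinicus,(Rhinolophus_affinis,Rhinolophus_pearsonii)))),((Hipposideros_cineraceus,(Hipposideros_pomona,(Hipposideros_armiger,Hipposideros_pratti))),Aselliscus_stoliczkanus)),((Megaderma_lyra,Megaderma_spasma),Rhinopoma_hardwickii))),((Taphozous_melanopogon,Emballonura_raffrayana),(((Mormoops_megalophylla,Pteronotus_davyi),(Desmodus_rotundus,((Artibeus_jamaicensis,Artibeus_lituratus),(Leptonycteris_yerbabuena,(Anoura_geoffroyi,Carollia_perspicillata))))),(((Scotophilus_kuhlii,(Myotis_ricketti,Murina_leucogaster)),Miniopterus_fuliginosus),(Tadarida_brasiliensis,Tadarida_plicata)))));
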
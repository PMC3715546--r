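species	family	status
Cynopterus_sphinx	Pteropodidae	functional
Rousettus_leschenaultii	Pteropodidae	functional
Rousettus_aegyptiacus	Pteropodidae	functional
Eonycteris_spelaea	Pteropodidae	functional
Pteropus_giganteus	Pteropodidae	functional
Dobsonia_viridis	Pteropodidae	functional
Rhinolophus_ferrumequinum	Rhinolophidae	nonfunctional
Rhinolophus_pusillus	Rhinolophidae	nonfunctional
Rhinolophus_sinicus	Rhinolophidae	nonfunctional
Rhinolophus_affinis	Rhinolophidae	nonfunctional
Rhinolophus_pearsonii	Rhinolophidae	nonfunctional
Hipposideros_cineraceus	Hipposideridae	nonfunctional
Hipposideros_armiger	Hipposideridae	nonfunctional
Hipposideros_pratti	Hipposideridae	nonfunctional
Hipposideros_pomona	Hipposideridae	nonfunctional
Aselliscus_stoliczkanus	Hipposideridae	nonfunctional
Megaderma_lyra	Megadermatidae	functional
Megaderma_spasma	Megadermatidae	functional
Rhinopoma_hardwickii	Rhinopomatidae	functional
Mormoops_megalophylla	Mormoopidae	functional
Pteronotus_davyi	Mormoopidae	functional
Desmodus_rotundus	Phyllostomidae	nonfunctional
Artibeus_jamaicensis	Phyllostomidae	functional
Artibeus_lituratus	Phyllostomidae	functional
Leptonycteris_yerbabuena	Phyllostomidae	functional
Anoura_geoffroyi	Phyllostomidae	functional
Carollia_perspicillata	Phyllostomidae	functional
Scotophilus_kuhlii	Vespertilionidae	nonfunctional
Myotis_ricketti	Vespertilionidae	nonfunctional
Murina_leucogaster	Vespertilionidae	nonfunctional
Miniopterus_fuliginosus	Miniopteridae	nonfunctional
Tadarida_brasiliensis	Molossidae	functional
Tadarida_plicata	Molossidae	functional
Taphozous_melanopogon	Emballonuridae	functional
Emballonura_raffrayana	Emballonuridae	functional
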
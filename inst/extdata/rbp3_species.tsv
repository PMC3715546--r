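species	family	status
Cynopterus_sphinx	Pteropodidae	functional
Rousettus_leschenaultii	Pteropodidae	functional
Eonycteris_spelaea	Pteropodidae	functional
Rhinolophus_luctus	Rhinolophidae	nonfunctional
Rhinolophus_pearsonii	Rhinolophidae	nonfunctional
Rhinolophus_pusillus	Rhinolophidae	nonfunctional
Rhinolophus_sinicus	Rhinolophidae	nonfunctional
Hipposideros_armiger	Hipposideridae	nonfunctional
Hipposideros_pratti	Hipposideridae	nonfunctional
Megaderma_lyra	Megadermatidae	functional
Megaderma_spasma	Megadermatidae	functional
Mormoops_megalophylla	Mormoopidae	functional
Pteronotus_davyi	Mormoopidae	nonfunctional
Pteronotus_parnellii	Mormoopidae	nonfunctional
Artibeus_jamaicensis	Phyllostomidae	functional
Pipistrellus_abramus	Vespertilionidae	nonfunctional
Tadarida_brasiliensis	Molossidae	functional
Emballonura_raffrayana	Emballonuridae	functional
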
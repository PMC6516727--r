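common,scientific,group,iucn,esa,natureserve,guild
Blue whale,Balaenoptera musculus,Baleen whales,VU,EN,G3G4,
Bryde's whale,Balaenoptera edeni,Baleen whales,DD,,G4,
Fin whale,Balaenoptera physalus,Baleen whales,EN,EN,G3G4,
Humpback whale,Megaptera novaeangliae,Baleen whales,LC,,G4,
Minke whale,Balaenoptera acutorostrata,Baleen whales,LC,,G5,
North Atlantic right whale,Eubalaena glacialis,Baleen whales,EN,EN,G1,
Sei whale,Balaenoptera borealis,Baleen whales,EN,EN,G3,
Blainville's beaked whale,Mesoplodon densirostris,Beaked and sperm whales,DD,,G4,Beaked whales
Cuvier's beaked whale,Ziphius cavirostris,Beaked and sperm whales,LC,,G4,Beaked whales
Gervais beaked whale,Mesoplodon europaeus,Beaked and sperm whales,DD,,G3,Beaked whales
Sowerby's beaked whale,Mesoplodon bidens,Beaked and sperm whales,DD,,G3,Beaked whales
True's beaked whale,Mesoplodon mirus,Beaked and sperm whales,DD,,G3,Beaked whales
Dwarf sperm whale,Kogia sima,Beaked and sperm whales,DD,,G4,Kogia whales
Pygmy sperm whale,Kogia breviceps,Beaked and sperm whales,DD,,G4,Kogia whales
Northern bottlenose whale,Hyperoodon ampullatus,Beaked and sperm whales,DD,,G4,
Sperm whale,Physeter macrocephalus,Beaked and sperm whales,VU,EN,G3G4,
False killer whale,Pseudorca crassidens,Large delphinoids,DD,,G4,
Killer whale,Orcinus orca,Large delphinoids,DD,EN,G4G5,
Melon headed whale,Peponocephala electra,Large delphinoids,LC,,G4,
"Pilot whale, long-finned",Globicephala melas,Large delphinoids,DD,,G5,Pilot whales
"Pilot whale, short-finned",Globicephala macrorhynchus,Large delphinoids,DD,,G5,Pilot whales
Risso's dolphin,Grampus griseus,Small delphinoids,LC,,G5,
Atlantic spotted dolphin,Stenella frontalis,Small delphinoids,DD,,G5,
Atlantic white-sided dolphin,Lagenorhynchus acutus,Small delphinoids,LC,,G4,
Common bottlenose dolphin,Tursiops truncatus,Small delphinoids,LC,,G5,
Clymene dolphin,Stenella clymene,Small delphinoids,DD,,G4,
Fraser's dolphin,Lagenodelphis hosei,Small delphinoids,LC,,G4,
Harbor porpoise,Phocoena phocoena,Small delphinoids,LC,,G4G5,
Pantropical spotted dolphin,Stenella attenuata,Small delphinoids,LC,,G5,
Rough-toothed dolphin,Steno bredanensis,Small delphinoids,LC,,G4,
Short-beaked common dolphin,Delphinus delphis,Small delphinoids,LC,,G5,
Spinner dolphin,Stenella longirostris,Small delphinoids,DD,,G5,
Striped dolphin,Stenella coeruleoalba,Small delphinoids,LC,,G5,
White-beaked dolphin,Lagenorhynchus albirostris,Small delphinoids,LC,,G4,
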
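common,scientific
Great Black-backed Gull,Larus marinus
Herring Gull,Larus argentatus
Black Scoter,Melanitta nigra
Black-legged Kittiwake,Rissa tridactyla
Common Loon,Gavia immer
Northern Gannet,Morus bassanus
Red-throated Loon,Gavia stellata
Common Eider,Somateria mollissima
Common Tern,Sterna hirundo
Razorbill,Alca torda
Roseate Tern,Sterna dougallii
White-winged Scoter,Melanitta fusca
Leach's Storm Petrel,Oceanodroma leucorhoa
Long-tailed Duck,Clangula hyemalis
Pomarine Jaeger,Stercorarius pomarinus
Cory's Shearwater,Calonectris diomedea
Dovekie,Alle alle
Great Shearwater,Puffinus gravis
Northern Fulmar,Fulmarus glacialis
Sooty Shearwater,Puffinus griseus
Wilson's Storm Petrel,Oceanites oceanicus
Bonaparte's gull,Chroicocephalus philadelphia
Double-crested cormorant,Phalacrocorax auritus
Laughing gull,Larus atricilla
Red phalarope,Phalaropus fulicarius
Ring-billed gull,Larus delawarensis
Surf scoter,Melanitta perspicillata
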
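common,scientific,channel,rank,value
Great Black-backed Gull,Larus marinus,Collision,Very high,5
Herring Gull,Larus argentatus,Collision,Very high,5
Black Scoter,Melanitta nigra,Displacement,High,4
Black-legged Kittiwake,Rissa tridactyla,Collision,High,4
Common Loon,Gavia immer,Displacement,High,4
Northern Gannet,Morus bassanus,Collision,High,4
Red-throated Loon,Gavia stellata,Displacement,High,4
Common Eider,Somateria mollissima,Displacement,Moderate,3
Common Tern,Sterna hirundo,Collision,Moderate,3
Razorbill,Alca torda,Displacement,Moderate,3
Roseate Tern,Sterna dougallii,Both,Moderate,3
White-winged Scoter,Melanitta fusca,Displacement,Moderate,3
Leach's Storm Petrel,Oceanodroma leucorhoa,Collision,Low,2
Long-tailed Duck,Clangula hyemalis,Displacement,Low,2
Pomarine Jaeger,Stercorarius pomarinus,Collision,Low,2
Cory's Shearwater,Calonectris diomedea,Both,Very low,1
Dovekie,Alle alle,Both,Very low,1
Great Shearwater,Puffinus gravis,Both,Very low,1
Northern Fulmar,Fulmarus glacialis,Both,Very low,1
Sooty Shearwater,Puffinus griseus,Both,Very low,1
Wilson's Storm Petrel,Oceanites oceanicus,Both,Very low,1
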
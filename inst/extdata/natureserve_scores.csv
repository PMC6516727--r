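rank,description,score
G1,Critically imperiled,100
G1G2,,87
G2,Imperiled,75
G2G3,,63
G3,Vulnerable,51
G3G4,,38
G4,Apparently secure,26
G4G5,,13
G5,Secure,1
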
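name,species,lipid_class,formula,adduct,observed_mz,fragments
PE(22:6/18:1),cod,PE,C45H76NO8P,[M-H]-,788.5,327.24;281.25;153.00
PS(18:1/18:0),cod,PS,C42H80NO10P,[M-H]-,788.5,283.26;281.25;153.00
PS(20:1/16:0),cod,PS,C42H80NO10P,[M-H]-,788.5,309.28;255.23;153.00
unknown 817.5,coley,unknown,,,817.5,327.24;283.25;281.25;255.23;229.20
PE(22:6/20:4),haddock,PE,C47H74NO8P,[M-H]-,810.5,327.24;303.24;283.25;153.00
PE(22:5/20:5),haddock,PE,C47H74NO8P,[M-H]-,810.5,301.22;257.23;153.00
PS(20:4/18:0),haddock,PS,C44H78NO10P,[M-H]-,810.5,303.24;283.25;153.00
unknown 629.5,pollock,unknown,,,629.5,327.24;301.22;283.25
DHA dimer FA(22:6),pollock,FA,C22H32O2,[2M-H]-,655.5,327.24;283.25;229.20
unknown 667.5,pollock,unknown,,,667.5,339.21;327.24;301.22;283.25;257.24
PE(22:6/18:0),whiting,PE,C45H78NO8P,[M-H]-,790.5,327.24;283.25
PS(18:0/18:0),whiting,PS,C42H82NO10P,[M-H]-,790.5,283.25
unknown 701.42,whiting,unknown,,,701.42,480.33;463.24;255.25
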
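# Residue-name dictionaries shared across modules.  Residue category is
# determined solely by residue name against these fixed sets (unknown
# residues with a peptide backbone count as non-standard amino acids).

.standardAA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")
.nucleotides <- c("A", "C", "G", "U", "I",
                  "DA", "DC", "DG", "DT", "DU", "DI")
.waters <- c("HOH", "WAT", "DOD", "H2O")

.aa321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.nuc1 <- c(A = "A", C = "C", G = "G", U = "U", I = "I",
           DA = "A", DC = "C", DG = "G", DT = "T", DU = "U", DI = "I")

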
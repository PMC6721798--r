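>FTL_5UTR_synthetic_standin
AAAACUCCAUGUGUAGUCCCGGAAGUAGAAUCUUGCACUCGGCCUUUCCAGGUCUCGUGA
ACCCCCUGCACGCCCUAAAGUACAAUUAGGAUAUUCAUCCCUACACUGUAUAUGCCGAAC
GUUCUAAUAAACGACUUAGCAACAAGUCGCCUAGAAAGGUACCGCUGGCAUAUCACGCCU
CCCGCUUGCCGUCUUCAACU
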
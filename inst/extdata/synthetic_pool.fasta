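>syn0001
AAAGAGAUUGUUAACCGUAGGAUC
>syn0002
CAUUAGAGGUUAGCGUACUCAUA
>syn0003
CGCCACUGUCCCCAUGUUAG
>syn0004
CGAAUUGCUGGCUAUUCCCACC
>syn0005
CUUAAAGCCCCUUUGGUCGGC
>syn0006
CGCCUACGUUAUUCAGGGGUGA
>syn0007
GAAGUUUUCGUUGAUUGAACAU
>syn0008
AACCCCAGGCAUGUUAGUCACGAA
>syn0009
UCCGUCCCUCCUACCACAGAAG
>syn0010
UCGGCGGCGUAGCAGUGGUCGCGGU
>syn0011
GGCAUUCAACGAUUAGAUGCGUA
>syn0012
AAGAAUACGAAAUGCGCCACG
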
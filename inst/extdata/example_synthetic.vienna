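>t5
AUACACAUAGCGCAUCGCUGGAGAAAUCUGGCUCUCCACGGUCCCUAAACCAGAUUAAGACUACUGUAAGAAUAUGCCAAAACAUGUAUGAUAGGCUAAACUUGUCUUGGUGGUGGUUGU
(((((((((((((((....................)))))))))))))))......................................................................
>t2
AUACACAUAGCGCAUCGCUGGAGAAAUCUGGCUCUCCACGGUCCCUGAACCAGAUUAAGACUACCGUAAGAAUAUGCCAAAACAUGUAUGAUAGGGUAAACUUGUCUUCGUGGUGGUUGU
(((((((((((((((....................)))))))))))))))......................................................................
>t8
AUACACAUAGCGCAUCGCUGGAGAAAUCUGGCUCUCCAGGCUCCCUUAACCUGAUUAAGACUACUAUAAGAAUAUGCCAAAACAUGUUUGAUUAGGUAAGCUUGUCCUGGUGGUGGUUGU
(((((((((((((((....................)))))))))))))))......................................................................
>t4
AUACAAAUAGCGCAGCGCGGGAGUAAUCUGGCUUUCCAGUGUCCCUUAUCCUUAUGAGGACUACUAUAAGCAAAUGCCAAAACAUGUUUGAUAGGAUAAGCUUGUCUAGGUGGUGGCUGU
(((((((((((((((....................)))))))))))))))......................................................................
>t1
AUACAAAUAGCGCACCGCGGGAGUAAUCUGGCUUUCCCGUGUCCCCUAUCCUUAUGAGCACUACUAUAAGUCAAUGCCAAAACAUGUUUGAUAGGAUAAACUUGACUAGGAGGUGGCUGU
(((((((((((((((....................)))))))))))))))......................................................................
>t9
AUACAAAUAGCGCAGCGCGGGAGUAAUCUGGCUUUCCAGUGUCCCUUAUCCUUAUGAGGACUACUAUAAGCAAAUGCCAAAACAUGUUUGAUAGGAUAAGCUUGUCUAGGUGGUGGCUGU
(((((((((((((((....................)))))))))))))))......................................................................
>t3
AUACACAUAGCGCAUCGCUGGAGAAAUCUGGCUCUCCACGGUCGCUUUACCAGAAUAAGACUACUAUAAGAAUAAGCCAAAACAUGUUUGAUAGGGUAAACUUGUCUUGGUGGUGGUUGU
(((((((((((((((....................)))))))))))))))......................................................................
>t10
AUACACAUAGCGCAUCGCUGGAGAAAUCUGGCUCUCCACGGUCCCUUUACCAGAUUAAGACUACUAUAAGAAUAUGCCAAAUCGGGUUGGAUAGGGUAAACUUGGCUUGGUGGUGGUUGU
(((((((((((((((....................)))))))))))))))......................................................................
>t6
AUACACAUAGCGCAUCGCUGGAGAAAUCUGGCUAUCCACGGUCCCUUUACCAGAUUAAGAAUACUAUAAGCAUAUGCCAAAUGGUAUUGGAUAGGGAAAACUUGUCUUGGUGGUGGUAGC
(((((((((((((((....................)))))))))))))))......................................................................
>t7
AUACAUAUAGCGCAUCGCUGGAGAAAUCUGGCUAUCCACGGUCCCUUUACCAGAUUAAGUAUACUAUAAGCAUAUGCCAAAUGGUACUGGAUAGGGAAAACUUGUCUUGGUGGUAGUAGC
(((((((((((((((....................)))))))))))))))......................................................................
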
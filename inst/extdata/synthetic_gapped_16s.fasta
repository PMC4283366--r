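>carteri_1
ACGTAC-TACGNTACGT?CG
>carteri_2
ACGTACGTACGATACGTACG
>ivonicus_1
ACTTACGTACGATACGAACG
>yuna
ACTTACGTACGATAC-AACG
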
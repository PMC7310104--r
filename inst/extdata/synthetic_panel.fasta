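>amp01
TGGTGTTCACCATTCACAAAAGCAAGCAATAACAGACAGCCATCTTAGGACGTGGAATAATTGTCCATAGACGTGAAGAA
ATACGCTACTCAAGAGTCTAGATACA
>amp02
CATCCATACACAGATCCCTAATGGGAAGCTATCGTATTTTCAGTAATAAGCACAAGTTCATCTGTAGTACTGACCGGAAA
AAAATTCCCAGACATTACACTTCTACACGTCTACTCCGAACAGCTACCTATTAATCAG
>amp03
TGATTACCAAAAGTGATCATATATCCCAGCGATTCACAAGTGCACAACAAGTTAACAACATCTTCCTAACTGATCCCCTG
CGTTTTGTCTCATAGCTGGAGGGCATTCGCCGTGAAGAATAGGTCACTGACAGCCCAGTCA
>amp04
ATTCCTGAACACACATGCAACGGCACCTATCATCTTTATGTCGTTGGCCAGTTTTGTATATATATGACCGCCGACGATCC
AGGCACTCCTTTCATCGCAATCTAGTACTCTCAGATAAGCTGGA
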
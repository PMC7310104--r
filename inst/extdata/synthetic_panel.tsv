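id	chrom	start	end	fwd_primer_len	rev_primer_len	ref_seq
amp01	chrS	0	106	20	20	TGGTGTTCACCATTCACAAAAGCAAGCAATAACAGACAGCCATCTTAGGACGTGGAATAATTGTCCATAGACGTGAAGAAATACGCTACTCAAGAGTCTAGATACA
amp02	chrS	1000	1138	20	20	CATCCATACACAGATCCCTAATGGGAAGCTATCGTATTTTCAGTAATAAGCACAAGTTCATCTGTAGTACTGACCGGAAAAAAATTCCCAGACATTACACTTCTACACGTCTACTCCGAACAGCTACCTATTAATCAG
amp03	chrS	2000	2141	20	20	TGATTACCAAAAGTGATCATATATCCCAGCGATTCACAAGTGCACAACAAGTTAACAACATCTTCCTAACTGATCCCCTGCGTTTTGTCTCATAGCTGGAGGGCATTCGCCGTGAAGAATAGGTCACTGACAGCCCAGTCA
amp04	chrS	3000	3124	20	20	ATTCCTGAACACACATGCAACGGCACCTATCATCTTTATGTCGTTGGCCAGTTTTGTATATATATGACCGCCGACGATCCAGGCACTCCTTTCATCGCAATCTAGTACTCTCAGATAAGCTGGA
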
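name	forward	reverse	unit_length
family0	CCGCCAAATGTGTTAGGAATG	CCTGTTGAAAGAGGCCAAAAAC	360
family38	AAAAAAAGGGATTATTGTATATTTTG	CGGTTCGGAATTTTCCAC	47
family10	AAACCCTACAATTGTTCTG	CTCTCCGGTGTGTATTC	84
family5	GTTCTAAATATGGGGCCTACCTT	CATCTTGGCAGAACCCTTTTC	120
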
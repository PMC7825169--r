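>lsu_ref_synthetic synthetic 23S rRNA 5-prime fragment reference (110 nt)
CCACCTCCTTCGTGAGAAATTCTCGATCGCGGCTCTCCCTTCTAAAAGTAGCTCAGCTCCGAATTGTTCG
CCCGCACAATCACAGGAATCCAGCGGGTTCCCCCATTCGG
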
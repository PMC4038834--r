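>Lep1_core_synthetic synthetic 134-bp stand-in core consensus (not the published sequence)
TCATGGTTTCTCTAACTTAATAACAACAGAGTCAGGTAATTAGTGTTTTTATAGAAGAGG
TGCTTAATTGAAGATAGAATGTAATTTTTCTTCGATCGTTCTATAATACTAGATCAAGCC
CTGTCCTTTACAAT
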
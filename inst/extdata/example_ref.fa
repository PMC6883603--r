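>toy1 toy contig with homopolymer run
GCATTTAC
>toy2 toy contig with dinucleotide repeat
ACGTATATATATGCCA
>toy3 mixed toy contig
TTGACCCCCGATTACAGGAAATTTCCGG
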
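>palindromic_4mer
ACGT
>odd_k_self_complemental_nodes
AATAA
>even_k_mixed
ACGTACGT
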
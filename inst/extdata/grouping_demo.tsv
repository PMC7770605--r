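leaf_id	group_acronym
5	HIP
6	HIP
7	HIP
8	NCX
9	NCX
10	NCX
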
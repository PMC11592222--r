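group	n_case	n_control
1	10	30
2	14	30
3	15	29
4	21	30
5-6	49	58
7	17	30
8	32	30
9	42	29
10	70	30
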
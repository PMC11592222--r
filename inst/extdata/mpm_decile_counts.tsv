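group	n_case	n_control
1	13	14
2	18	9
3	18	9
4	14	13
5	21	6
6	17	10
7	13	14
8	21	6
9	20	7
10	22	5
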
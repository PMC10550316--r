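mutation_type	total
C>A	994
C>G	653
C>T	2768
T>A	1084
T>C	1768
T>G	650
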
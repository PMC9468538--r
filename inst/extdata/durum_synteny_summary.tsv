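# Syntenic target chromosomes per breeding QTL hotspot.
# Prefixes: bd = Brachypodium distachyon, os = Oryza sativa, zm = Zea mays.
hotspot_id	chromosome	target_chromosomes
1	1A	bd1,bd2,bd4,os1,os5,os11,os12,zm9
4	1B	bd2,os5,os7
5	1B	bd4,bd2
10	1B	bd2,bd5,os5
15	2A	bd5
26	2B	bd5,os4,zm2
33	3B	bd2,os1,os5,os6
35	3B	bd2,bd3,os1,zm9
47	4B	bd1,os3
52	4B	bd1,os3,zm1
57	5A	bd1,bd3,bd4,os3,os9,zm2,zm5
64	6A	bd1,os6,os7
73	6A	bd1,bd3,bd5,os2,os3,os8,os10,zm5
79	7A	bd1,bd3,os8
81	7A	bd1,os6
85	7A	bd1,os6
92	7B	bd3
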
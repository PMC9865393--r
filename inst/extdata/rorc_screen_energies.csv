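ligand_id,receptor_id,energy
4,7NPC,-7.9
4,7NP5,-8.2
4,7KXD,-8.6
5,7NPC,-6.5
5,7NP5,-6.9
5,7KXD,-6.7
6,7NPC,-8.6
6,7NP5,-8.1
6,7KXD,-8.7
7,7NPC,-9.2
7,7NP5,-10.0
7,7KXD,-8.7
8,7NPC,-8.8
8,7NP5,-9.0
8,7KXD,-9.2
9,7NPC,-8.0
9,7NP5,-8.2
9,7KXD,-8.5
10,7NPC,-10.0
10,7NP5,-9.1
10,7KXD,-9.2
11,7NPC,-8.7
11,7NP5,-8.8
11,7KXD,-10.0
12,7NPC,-9.9
12,7NP5,-9.5
12,7KXD,-10.0
14,7NPC,-6.6
14,7NP5,-6.9
14,7KXD,-7.2
15,7NPC,-7.0
15,7NP5,-7.1
15,7KXD,-7.3
16,7NPC,-7.5
16,7NP5,-7.4
16,7KXD,-7.7
17,7NPC,-7.0
17,7NP5,-7.1
17,7KXD,-7.3
18,7NPC,-9.7
18,7NP5,-8.1
18,7KXD,-8.3
19,7NPC,-8.8
19,7NP5,-10.0
19,7KXD,-10.0
20,7NPC,-9.5
20,7NP5,-10.0
20,7KXD,-9.6
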
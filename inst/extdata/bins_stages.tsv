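name	older	younger
Pennsylvanian	323.2	298.9
Cisuralian	298.9	273
Guadalupian	273	259.5
Lopingian	259.5	251.9
Early Triassic	251.9	247.2
Middle Triassic	247.2	237
Late Triassic	237	201.4
Early Jurassic	201.4	174.7
Middle Jurassic	174.7	161.5
Late Jurassic	161.5	145
Early Cretaceous	145	100.5
Late Cretaceous	100.5	66
Paleocene	66	56
Eocene	56	33.9
Oligocene	33.9	23
Neogene+	23	0
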
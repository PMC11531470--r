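gene_a	gene_b	mean_delta	sd_delta
RNU6	miR-103a-3p	0.8783	2.418
RNU6	5sRNA	5.7	1.761
RNU6	RNU1A1	4.268	1.867
RNU6	SNORD44	1.797	1.244
RNU6	miR-532-5p	-3.505	2.406
miR-103a-3p	RNU6	-0.8783	2.418
miR-103a-3p	5sRNA	4.822	1.295
miR-103a-3p	RNU1A1	3.39	2.789
miR-103a-3p	SNORD44	0.9183	1.809
miR-103a-3p	miR-532-5p	-4.383	2.424
5sRNA	RNU6	-5.7	1.761
5sRNA	miR-103a-3p	-4.822	1.295
5sRNA	RNU1A1	-1.432	2.28
5sRNA	SNORD44	-3.903	1.907
5sRNA	miR-532-5p	-9.205	2.596
RNU1A1	RNU6	-4.268	1.867
RNU1A1	miR-103a-3p	-3.39	2.789
RNU1A1	5sRNA	1.432	2.28
RNU1A1	SNORD44	-2.472	2.085
RNU1A1	miR-532-5p	-7.773	1.441
SNORD44	RNU6	-1.797	1.244
SNORD44	miR-103a-3p	-0.9183	1.809
SNORD44	5sRNA	3.903	1.907
SNORD44	RNU1A1	2.472	2.085
SNORD44	miR-532-5p	-5.302	1.865
miR-532-5p	RNU6	3.505	2.406
miR-532-5p	miR-103a-3p	4.383	2.424
miR-532-5p	5sRNA	9.205	2.596
miR-532-5p	RNU1A1	7.773	1.441
miR-532-5p	SNORD44	5.302	1.865
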
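gene_a	gene_b	mean_delta	sd_delta
RNU6	miR-103a-3p	0.3925	2.339
RNU6	5sRNA	8.302	3.8
RNU6	RNU1A1	4.632	2.233
RNU6	SNORD44	1.361	1.89
RNU6	miR-532-5p	-4.826	2.416
miR-103a-3p	RNU6	-0.3925	2.339
miR-103a-3p	5sRNA	7.909	3.297
miR-103a-3p	RNU1A1	4.24	2.252
miR-103a-3p	SNORD44	0.9681	2.066
miR-103a-3p	miR-532-5p	-5.219	1.123
5sRNA	RNU6	-8.302	3.8
5sRNA	miR-103a-3p	-7.909	3.297
5sRNA	RNU1A1	-3.67	2.268
5sRNA	SNORD44	-6.941	4.189
5sRNA	miR-532-5p	-13.13	3.166
RNU1A1	RNU6	-4.632	2.233
RNU1A1	miR-103a-3p	-4.24	2.252
RNU1A1	5sRNA	3.67	2.268
RNU1A1	SNORD44	-3.271	2.702
RNU1A1	miR-532-5p	-9.458	2.126
SNORD44	RNU6	-1.361	1.89
SNORD44	miR-103a-3p	-0.9681	2.066
SNORD44	5sRNA	6.941	4.189
SNORD44	RNU1A1	3.271	2.702
SNORD44	miR-532-5p	-6.187	2.268
miR-532-5p	RNU6	4.826	2.416
miR-532-5p	miR-103a-3p	5.219	1.123
miR-532-5p	5sRNA	13.13	3.166
miR-532-5p	RNU1A1	9.458	2.126
miR-532-5p	SNORD44	6.187	2.268
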
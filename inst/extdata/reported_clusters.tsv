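map	region	brodmann	peak_x	peak_y	peak_z	peak_t	extent_voxels
lpfcd	Left Calcarine/Lingual gyrus	17/18	-3	-90	0	-4.0559	36
lnfcd	Left Lingual gyrus	18	-9	-78	-6	-4.122	41
spfcd	Right Angular gyrus	39/40	54	-51	33	3.8163	44
snfcd	Left Superior frontal gyrus, medial	8	-3	30	51	4.4059	39
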
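progeny,blup_gy,genotypic_value_gy,blup_id,genotypic_value_id
135,1423,4890,-17.3,33.7
145,1059,4525,-15.8,35.2
85,1020,4486,-10.9,40.1
150,746,4212,-11.2,39.8
87,706,4173,-10.6,40.4
4,626,4092,-9.4,41.7
44,604,4071,-9.1,41.9
82,580,4047,-8.6,42.4
96,568,4035,-8.5,42.5
105,565,4031,-8.4,42.6
selected_mean,558,4025,-7.9,43.1
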
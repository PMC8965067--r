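fragment_id	label	motif_start	motif_end
pos_0001	dimer	18	23
pos_0002	dimer	35	40
pos_0003	dimer	28	33
neg_0001	non-dimer		
neg_0002	non-dimer		
neg_0003	non-dimer		
neg_0004	non-dimer		
neg_0005	non-dimer		
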
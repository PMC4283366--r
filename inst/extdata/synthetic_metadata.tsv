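id	taxon	locality_code	lot	lineage
carteri_1	carteri	c1	LOT-CA01	carteri
carteri_2	carteri	c2	LOT-CA02	carteri
ivonicus_1	ivonicus	i1	LOT-IV01	ivonicus_yuna
yuna	yuna	y1	LOT-YU01	ivonicus_yuna
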
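sample	site	period	c14_bp	genotype	replicates
LPA01	La Pasiega	Magdalenian	NA	TT	
LCH01	La Chora	Magdalenian	NA	TT	
ERR01	Erralla	Magdalenian	12319	TT	TT;TT
MAR01	Marizulo	Neolithic	5285	TT	TT;TT
SJAPL01	SJAPL	Late-Neolithic	5070	TT	TT;TT
SJAPL02	SJAPL	Late-Neolithic	5070	TT	TT;TT
SJAPL03	SJAPL	Late-Neolithic	5070	TT	TT;TT
SJAPL04	SJAPL	Late-Neolithic	5070	TT	TT;TT
SJAPL05	SJAPL	Late-Neolithic	5070	TT	TT;NA
SJAPL06	SJAPL	Late-Neolithic	5070	TT	
SJAPL07	SJAPL	Late-Neolithic	5070	TT	
SJAPL08	SJAPL	Late-Neolithic	5070	TT	
SJAPL09	SJAPL	Late-Neolithic	5070	TT	
SJAPL10	SJAPL	Late-Neolithic	5070	TT	
SJAPL11	SJAPL	Late-Neolithic	5070	TT	
SJAPL12	SJAPL	Late-Neolithic	5070	TT	
SJAPL13	SJAPL	Late-Neolithic	5070	TT	
SJAPL14	SJAPL	Late-Neolithic	5070	TT	
SJAPL15	SJAPL	Late-Neolithic	5070	TT	
SJAPL16	SJAPL	Late-Neolithic	5070	TT	
SJAPL17	SJAPL	Late-Neolithic	5070	TT	
LON01	Longar	Neolithic-Calcolithic	4445	TT	
LON02	Longar	Neolithic-Calcolithic	4445	TT	
LON03	Longar	Neolithic-Calcolithic	4445	TT	
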
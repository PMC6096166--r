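term	style	text	sense_rank
vascular	summary	consisting of a vessel or vessels	1
coryza	summary	an inflammation of the mucous membrane lining the nose (usually associated with nasal discharge)	1
attenuated	synonym	rarefy	1
attenuated	summary	reduced in strength or concentration	2
gastrointestine	summary	the stomach and intestine considered together	1
vessel	summary	a tube in which a body fluid circulates	1
kidney	summary	an organ that excretes urine	1
liver	summary	a large organ that secretes bile and processes nutrients	1
muscle	summary	animal tissue consisting of cells able to contract	1
intestine	summary	the part of the alimentary canal between the stomach and the anus	1
thirst	summary	a physiological need to drink	1
fever	summary	a rise of body temperature above the normal	1
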
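term	style	text	sense_rank
vascular	summary	perteneciente o relativo a los vasos del cuerpo	1
fiebre	summary	aumento de la temperatura del cuerpo por encima de la normal	1
sed	summary	necesidad fisiológica de beber	1
riñón	summary	órgano que excreta la orina	1
hígado	summary	órgano grande que segrega la bilis	1
músculo	summary	tejido capaz de contraerse	1
visión	summary	capacidad de ver	1
sangre	summary	líquido que circula por las venas y arterias	1
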
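form	position	definition	origin	language
pireto-	prefix	Forma prefija que significa fiebre	Latin or Greek	es
hiper-	prefix	Forma prefija que significa exceso o superioridad	Greek	es
hipo-	prefix	Forma prefija que significa debajo de lo normal	Greek	es
glic-	prefix	Forma prefija que significa azúcar	Greek	es
cardio-	prefix	Forma prefija que significa el corazón	Greek	es
anti-	prefix	Forma prefija que significa contra	Greek	es
a-	prefix	Forma prefija que significa sin, carencia de	Greek	es
gastro-	prefix	Forma prefija que significa el estómago	Greek	es
hepato-	prefix	Forma prefija que significa el hígado	Greek	es
nefro-	prefix	Forma prefija que significa el riñón	Greek	es
neuro-	prefix	Forma prefija que significa los nervios	Greek	es
osteo-	prefix	Forma prefija que significa hueso	Greek	es
mio-	prefix	Forma prefija que significa músculo	Greek	es
hemo-	prefix	Forma prefija que significa sangre	Greek	es
leuco-	prefix	Forma prefija que significa blanco	Greek	es
eritro-	prefix	Forma prefija que significa rojo	Greek	es
termo-	prefix	Forma prefija que significa calor	Greek	es
endo-	prefix	Forma prefija que significa dentro, interior	Greek	es
peri-	prefix	Forma prefija que significa alrededor de	Greek	es
poli-	prefix	Forma prefija que significa muchos	Greek	es
micro-	prefix	Forma prefija que significa pequeño	Greek	es
macro-	prefix	Forma prefija que significa grande	Greek	es
hemi-	prefix	Forma prefija que significa medio	Greek	es
dis-	prefix	Forma prefija que significa dificultad o anomalía	Greek	es
taqui-	prefix	Forma prefija que significa rápido	Greek	es
bradi-	prefix	Forma prefija que significa lento	Greek	es
-opsia	suffix	Forma sufija que significa visión	Greek	es
-dipsia	suffix	Forma sufija que significa sed	Greek	es
-itis	suffix	Forma sufija que significa inflamación	Greek	es
-osis	suffix	Forma sufija que significa proceso o condición anormal	Greek	es
-oma	suffix	Forma sufija que significa tumor	Greek	es
-patía	suffix	Forma sufija que significa enfermedad	Greek	es
-logía	suffix	Forma sufija que significa estudio de	Greek	es
-ectomía	suffix	Forma sufija que significa extirpación quirúrgica	Greek	es
-algia	suffix	Forma sufija que significa dolor	Greek	es
-penia	suffix	Forma sufija que significa deficiencia	Greek	es
-cito	suffix	Forma sufija que significa célula	Greek	es
-fagia	suffix	Forma sufija que significa acción de comer o tragar	Greek	es
-megalia	suffix	Forma sufija que significa agrandamiento	Greek	es
-plastia	suffix	Forma sufija que significa reparación quirúrgica	Greek	es
-scopia	suffix	Forma sufija que significa examen visual	Greek	es
-uria	suffix	Forma sufija que significa condición de la orina	Greek	es
-emia	suffix	Forma sufija que significa condición de la sangre	Greek	es
-ico	suffix	Forma sufija que significa relativo a	Greek	es
-al	suffix	Forma sufija que significa relativo a	Latin	es
-s	suffix	Forma sufija que indica plural	Latin	es
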
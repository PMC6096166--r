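form	position	definition	origin	language
adip-	prefix	Of or relating to fat or fatty tissue	Latin	en
hyper-	prefix	denotes something as extreme or beyond normal	Greek	en
hypo-	prefix	below normal, deficient	Greek	en
glyc-	prefix	sugar	Greek	en
glyco-	prefix	sugar	Greek	en
cardio-	prefix	the heart	Greek	en
anti-	prefix	against	Greek	en
a-	prefix	not, without	Greek	en
brady-	prefix	slow	Greek	en
tachy-	prefix	fast, rapid	Greek	en
dermato-	prefix	the skin	Greek	en
gastro-	prefix	the stomach	Greek	en
hepato-	prefix	the liver	Greek	en
nephro-	prefix	the kidney	Greek	en
neuro-	prefix	nerves, the nervous system	Greek	en
osteo-	prefix	bone	Greek	en
myo-	prefix	muscle	Greek	en
hemo-	prefix	blood	Greek	en
leuko-	prefix	white	Greek	en
erythro-	prefix	red	Greek	en
thermo-	prefix	heat	Greek	en
pyo-	prefix	pus	Greek	en
pyreto-	prefix	fever	Greek	en
endo-	prefix	within, inner	Greek	en
peri-	prefix	around, surrounding	Greek	en
poly-	prefix	many, much	Greek	en
micro-	prefix	small	Greek	en
macro-	prefix	large	Greek	en
hemi-	prefix	half	Greek	en
dys-	prefix	bad, difficult, abnormal	Greek	en
-dipsia	suffix	(condition of) thirst	Greek	en
-ic	suffix	pertaining to	Greek	en
-al	suffix	pertaining to	Latin	en
-er	suffix	one who, that which	English	en
-s	suffix	plural	English	en
-itis	suffix	inflammation	Greek	en
-osis	suffix	abnormal condition or process	Greek	en
-oma	suffix	tumor, mass	Greek	en
-pathy	suffix	disease	Greek	en
-ology	suffix	the study of	Greek	en
-ectomy	suffix	surgical removal	Greek	en
-algia	suffix	pain	Greek	en
-penia	suffix	deficiency	Greek	en
-cyte	suffix	cell	Greek	en
-genic	suffix	producing, originating	Greek	en
-megaly	suffix	enlargement	Greek	en
-phagia	suffix	eating, swallowing	Greek	en
-plasty	suffix	surgical repair	Greek	en
-scopy	suffix	visual examination	Greek	en
-uria	suffix	condition of the urine	Greek	en
-emia	suffix	blood condition	Greek	en
-tomy	suffix	cutting, incision	Greek	en
-phobia	suffix	fear	Greek	en
-gram	suffix	a record	Greek	en
-graphy	suffix	process of recording	Greek	en
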
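term	style	text	sense_rank
pheochromocytoma	summary	A usually benign, well-encapsulated, lobular, vascular tumor of chromaffin tissue of the Adrenal Medulla	1
hypertension	summary	high blood pressure	1
diabetes	summary	a disease in which there is too much sugar in the blood	1
myocardium	summary	the muscle tissue of the heart	1
edema	summary	swelling caused by fluid trapped in body tissue	1
analgesic	synonym	painkiller	1
pruritus	synonym	itching	1
dyspnea	summary	shortness of breath	1
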
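# Observation lexicon: surface<TAB>type[<TAB>mode]
# Lemma-mode entries are matched against token lemmas (so "infarcts"
# matches "infarct"); literal-mode entries match the surface
# case-insensitively (used for abbreviations).
# --- documented surface forms of the annotation scheme ---
infarct	ischaemic_stroke
infarction	ischaemic_stroke
ischaemic stroke	ischaemic_stroke
lacunar event	ischaemic_stroke
ischaemic event	ischaemic_stroke
POCI	ischaemic_stroke	literal
LACI	ischaemic_stroke	literal
TACI	ischaemic_stroke	literal
PACI	ischaemic_stroke	literal
haemorrhage	haemorrhagic_stroke
haemorrhagic stroke	haemorrhagic_stroke
intracerebral haemorrhage	haemorrhagic_stroke
bleed	haemorrhagic_stroke
stroke	stroke_unknown
cerebrovascular accident	stroke_unknown
CVA	stroke_unknown	literal
meningioma	tumour_meningioma
metastasis	tumour_metastasis
metastatic deposit	tumour_metastasis
tumour	tumour
mass	tumour
neoplasm	tumour
space-occupying lesion	tumour
glioma	tumour_glioma
glioblastoma	tumour_glioma
subdural haematoma	subdural_haematoma
subdural collection	subdural_haematoma
extra-axial collection	subdural_haematoma
subdural hygroma	subdural_haematoma
small vessel disease	small_vessel_disease
small vessel ischaemic change	small_vessel_disease
microangiopathy	small_vessel_disease
leukoaraiosis	small_vessel_disease
atrophy	atrophy
inter-cerebral volume loss	atrophy
volume loss	atrophy
cerebral involution	atrophy
microbleed	microbleed
microhaemorrhage	microbleed
micro-haemorrhage	microbleed
subarachnoid haemorrhage	subarachnoid_haemorrhage
subarachnoid blood	subarachnoid_haemorrhage
SAH	subarachnoid_haemorrhage	literal
haemorrhagic transformation	haemorrhagic_transformation
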
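# Declarative label rules: obs_type<TAB>loc<TAB>time<TAB>cue<TAB>label
# For each non-negated observation entity in the report body or conclusion,
# its location value (deep|cortical|none, from explicit mod-loc relations
# or nesting), time value (old|recent|none, from mod-time relations or
# nesting) and cue context are looked up against these rows in order; the
# first matching row selects its label.  "any" matches every value
# including none; "-" means the dimension is ignored.  The row mapping a
# deep ischaemic stroke with no time modifier to the "old" label encodes
# the default that such strokes are assumed old.
ischaemic_stroke	deep	recent	-	Ischaemic stroke, deep, recent
ischaemic_stroke	deep	old	-	Ischaemic stroke, deep, old
ischaemic_stroke	deep	none	-	Ischaemic stroke, deep, old
ischaemic_stroke	cortical	recent	-	Ischaemic stroke, cortical, recent
ischaemic_stroke	cortical	old	-	Ischaemic stroke, cortical, old
ischaemic_stroke	cortical	none	-	Ischaemic stroke, underspecified
ischaemic_stroke	none	any	-	Ischaemic stroke, underspecified
haemorrhagic_stroke	deep	recent	-	Haemorrhagic stroke, deep, recent
haemorrhagic_stroke	deep	old	-	Haemorrhagic stroke, deep, old
haemorrhagic_stroke	cortical	recent	-	Haemorrhagic stroke, lobar, recent
haemorrhagic_stroke	cortical	old	-	Haemorrhagic stroke, lobar, old
haemorrhagic_stroke	deep	none	-	Haemorrhagic stroke, underspecified
haemorrhagic_stroke	cortical	none	-	Haemorrhagic stroke, underspecified
haemorrhagic_stroke	none	any	-	Haemorrhagic stroke, underspecified
stroke_unknown	any	any	-	Stroke, underspecified
microbleed	deep	-	-	Microbleed, deep
microbleed	cortical	-	-	Microbleed, lobar
microbleed	none	-	-	Microbleed, underspecified
tumour_meningioma	-	-	-	Tumour, meningioma
tumour_metastasis	-	-	-	Tumour, metastasis
tumour_glioma	-	-	-	Tumour, glioma
tumour	-	-	-	Tumour, other
small_vessel_disease	-	-	-	Small vessel disease
atrophy	-	-	-	Atrophy
subdural_haematoma	-	-	-	Subdural haematoma
subarachnoid_haemorrhage	-	-	aneurysm	Subarachnoid haemorrhage, aneurysmal
subarachnoid_haemorrhage	-	-	-	Subarachnoid haemorrhage, other
haemorrhagic_transformation	-	-	-	Haemorrhagic transformation
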
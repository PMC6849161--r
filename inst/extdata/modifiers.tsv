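# Modifier lexicon: surface<TAB>type[<TAB>mode]
# Location: loc_deep vs loc_cortical; recency: time_old vs time_recent.
# Stroke-classification acronyms carry nested observation+modifier
# meaning and appear in both lexicons (literal mode).
old	time_old
previous	time_old
established	time_old
chronic	time_old
longstanding	time_old
mature	time_old
acute	time_recent
recent	time_recent
new	time_recent
fresh	time_recent
deep	loc_deep
thalamic	loc_deep
lacunar	loc_deep
subcortical	loc_deep
basal ganglia	loc_deep
internal capsule	loc_deep
pontine	loc_deep
brainstem	loc_deep
LACI	loc_deep	literal
cortical	loc_cortical
lobar	loc_cortical
peripheral	loc_cortical
POCI	loc_cortical	literal
TACI	loc_cortical	literal
PACI	loc_cortical	literal
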
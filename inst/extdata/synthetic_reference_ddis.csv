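drug1,drug2,source,severity
citalopram,quetiapine,lexicomp,D
citalopram,quetiapine,drugscom,Major
amiodarone,sotalol,lexicomp,X
amiodarone,sotalol,drugscom,Major
amiodarone,ciprofloxacin,drugscom,Major
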
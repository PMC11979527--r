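drug,credible_meds,uptodate
amiodarone,known,highest
sotalol,known,highest
citalopram,known,moderate
quetiapine,possible,moderate
ciprofloxacin,known,moderate
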
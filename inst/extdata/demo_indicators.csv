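"patient_id","icd","medication","restraints_sitter","mortality","cam"
"P001",-1,1,1,-1,1
"P002",-1,-1,-1,-1,-1
"P003",-1,-1,-1,-1,-1
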
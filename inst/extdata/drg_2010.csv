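code,reimbursement_eur
F49G,1085.33
F49A,6385.32
F24B,5108.25
F24A,7741.65
F19C,4603.30
F19A,7063.48
F08E,6834.49
T61B,1735.05
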
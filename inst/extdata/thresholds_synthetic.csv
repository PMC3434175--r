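# cuepool threshold table v1
subject_id,T_a,T_m,T_am
S4_synthetic,0.27,0.21,0.16
S5_synthetic,0.3,0.24,0.19
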
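# cuepool trial table v1
subject_id,condition,level,response
S1,audio,-0.5,down
S1,audio,-0.5,down
S1,audio,-0.5,down
S1,audio,-0.5,down
S1,audio,-0.5,down
S1,audio,-0.5,down
S1,audio,-0.5,down
S1,audio,-0.5,down
S1,audio,-0.5,down
S1,audio,-0.5,down
S1,audio,-0.4,up
S1,audio,-0.4,down
S1,audio,-0.4,down
S1,audio,-0.4,down
S1,audio,-0.4,down
S1,audio,-0.4,down
S1,audio,-0.4,down
S1,audio,-0.4,down
S1,audio,-0.4,down
S1,audio,-0.4,down
S1,audio,-0.3,down
S1,audio,-0.3,down
S1,audio,-0.3,down
S1,audio,-0.3,down
S1,audio,-0.3,down
S1,audio,-0.3,down
S1,audio,-0.3,down
S1,audio,-0.3,down
S1,audio,-0.3,down
S1,audio,-0.3,down
S1,audio,-0.2,up
S1,audio,-0.2,down
S1,audio,-0.2,down
S1,audio,-0.2,down
S1,audio,-0.2,down
S1,audio,-0.2,down
S1,audio,-0.2,down
S1,audio,-0.2,down
S1,audio,-0.2,up
S1,audio,-0.2,up
S1,audio,-0.1,down
S1,audio,-0.1,down
S1,audio,-0.1,up
S1,audio,-0.1,up
S1,audio,-0.1,down
S1,audio,-0.1,down
S1,audio,-0.1,up
S1,audio,-0.1,up
S1,audio,-0.1,down
S1,audio,-0.1,up
S1,audio,0.1,up
S1,audio,0.1,down
S1,audio,0.1,up
S1,audio,0.1,down
S1,audio,0.1,up
S1,audio,0.1,up
S1,audio,0.1,down
S1,audio,0.1,down
S1,audio,0.1,up
S1,audio,0.1,up
S1,audio,0.2,up
S1,audio,0.2,up
S1,audio,0.2,up
S1,audio,0.2,up
S1,audio,0.2,down
S1,audio,0.2,up
S1,audio,0.2,down
S1,audio,0.2,up
S1,audio,0.2,up
S1,audio,0.2,up
S1,audio,0.3,up
S1,audio,0.3,up
S1,audio,0.3,up
S1,audio,0.3,up
S1,audio,0.3,down
S1,audio,0.3,up
S1,audio,0.3,up
S1,audio,0.3,up
S1,audio,0.3,up
S1,audio,0.3,up
S1,audio,0.4,up
S1,audio,0.4,up
S1,audio,0.4,up
S1,audio,0.4,down
S1,audio,0.4,up
S1,audio,0.4,up
S1,audio,0.4,up
S1,audio,0.4,up
S1,audio,0.4,up
S1,audio,0.4,up
S1,audio,0.5,up
S1,audio,0.5,up
S1,audio,0.5,up
S1,audio,0.5,up
S1,audio,0.5,up
S1,audio,0.5,up
S1,audio,0.5,up
S1,audio,0.5,up
S1,audio,0.5,up
S1,audio,0.5,up
S1,motion,-0.5,down
S1,motion,-0.5,down
S1,motion,-0.5,down
S1,motion,-0.5,down
S1,motion,-0.5,down
S1,motion,-0.5,down
S1,motion,-0.5,down
S1,motion,-0.5,down
S1,motion,-0.5,down
S1,motion,-0.5,down
S1,motion,-0.4,down
S1,motion,-0.4,down
S1,motion,-0.4,down
S1,motion,-0.4,down
S1,motion,-0.4,down
S1,motion,-0.4,down
S1,motion,-0.4,down
S1,motion,-0.4,down
S1,motion,-0.4,down
S1,motion,-0.4,down
S1,motion,-0.3,down
S1,motion,-0.3,up
S1,motion,-0.3,down
S1,motion,-0.3,down
S1,motion,-0.3,down
S1,motion,-0.3,down
S1,motion,-0.3,down
S1,motion,-0.3,down
S1,motion,-0.3,down
S1,motion,-0.3,down
S1,motion,-0.2,down
S1,motion,-0.2,down
S1,motion,-0.2,down
S1,motion,-0.2,down
S1,motion,-0.2,down
S1,motion,-0.2,down
S1,motion,-0.2,down
S1,motion,-0.2,down
S1,motion,-0.2,down
S1,motion,-0.2,down
S1,motion,-0.1,down
S1,motion,-0.1,up
S1,motion,-0.1,down
S1,motion,-0.1,down
S1,motion,-0.1,down
S1,motion,-0.1,down
S1,motion,-0.1,up
S1,motion,-0.1,down
S1,motion,-0.1,down
S1,motion,-0.1,down
S1,motion,0.1,up
S1,motion,0.1,up
S1,motion,0.1,up
S1,motion,0.1,down
S1,motion,0.1,down
S1,motion,0.1,down
S1,motion,0.1,up
S1,motion,0.1,down
S1,motion,0.1,down
S1,motion,0.1,up
S1,motion,0.2,up
S1,motion,0.2,up
S1,motion,0.2,up
S1,motion,0.2,up
S1,motion,0.2,up
S1,motion,0.2,up
S1,motion,0.2,up
S1,motion,0.2,down
S1,motion,0.2,up
S1,motion,0.2,up
S1,motion,0.3,up
S1,motion,0.3,up
S1,motion,0.3,up
S1,motion,0.3,up
S1,motion,0.3,up
S1,motion,0.3,up
S1,motion,0.3,up
S1,motion,0.3,up
S1,motion,0.3,up
S1,motion,0.3,up
S1,motion,0.4,up
S1,motion,0.4,up
S1,motion,0.4,up
S1,motion,0.4,up
S1,motion,0.4,up
S1,motion,0.4,up
S1,motion,0.4,up
S1,motion,0.4,up
S1,motion,0.4,up
S1,motion,0.4,up
S1,motion,0.5,up
S1,motion,0.5,up
S1,motion,0.5,up
S1,motion,0.5,up
S1,motion,0.5,up
S1,motion,0.5,up
S1,motion,0.5,up
S1,motion,0.5,up
S1,motion,0.5,up
S1,motion,0.5,up
S1,both,-0.5,down
S1,both,-0.5,down
S1,both,-0.5,down
S1,both,-0.5,down
S1,both,-0.5,down
S1,both,-0.5,up
S1,both,-0.5,down
S1,both,-0.5,down
S1,both,-0.5,down
S1,both,-0.5,down
S1,both,-0.4,down
S1,both,-0.4,down
S1,both,-0.4,down
S1,both,-0.4,down
S1,both,-0.4,down
S1,both,-0.4,down
S1,both,-0.4,down
S1,both,-0.4,down
S1,both,-0.4,down
S1,both,-0.4,down
S1,both,-0.3,down
S1,both,-0.3,down
S1,both,-0.3,down
S1,both,-0.3,down
S1,both,-0.3,down
S1,both,-0.3,down
S1,both,-0.3,down
S1,both,-0.3,down
S1,both,-0.3,down
S1,both,-0.3,down
S1,both,-0.2,down
S1,both,-0.2,down
S1,both,-0.2,down
S1,both,-0.2,up
S1,both,-0.2,down
S1,both,-0.2,down
S1,both,-0.2,up
S1,both,-0.2,down
S1,both,-0.2,down
S1,both,-0.2,down
S1,both,-0.1,up
S1,both,-0.1,down
S1,both,-0.1,down
S1,both,-0.1,down
S1,both,-0.1,down
S1,both,-0.1,down
S1,both,-0.1,down
S1,both,-0.1,down
S1,both,-0.1,up
S1,both,-0.1,up
S1,both,0.1,up
S1,both,0.1,up
S1,both,0.1,up
S1,both,0.1,up
S1,both,0.1,up
S1,both,0.1,up
S1,both,0.1,down
S1,both,0.1,up
S1,both,0.1,down
S1,both,0.1,up
S1,both,0.2,down
S1,both,0.2,up
S1,both,0.2,up
S1,both,0.2,up
S1,both,0.2,up
S1,both,0.2,up
S1,both,0.2,up
S1,both,0.2,up
S1,both,0.2,up
S1,both,0.2,down
S1,both,0.3,up
S1,both,0.3,up
S1,both,0.3,up
S1,both,0.3,up
S1,both,0.3,up
S1,both,0.3,up
S1,both,0.3,up
S1,both,0.3,up
S1,both,0.3,up
S1,both,0.3,up
S1,both,0.4,up
S1,both,0.4,up
S1,both,0.4,up
S1,both,0.4,up
S1,both,0.4,up
S1,both,0.4,up
S1,both,0.4,up
S1,both,0.4,up
S1,both,0.4,up
S1,both,0.4,up
S1,both,0.5,up
S1,both,0.5,up
S1,both,0.5,up
S1,both,0.5,up
S1,both,0.5,up
S1,both,0.5,up
S1,both,0.5,up
S1,both,0.5,up
S1,both,0.5,up
S1,both,0.5,up
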
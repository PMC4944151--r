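{"1C4":[1.35,2.04,2.19,1.69],"2SO":[5.55,8.48,4.82,3.14],"4C1":[7.85,8.03,8.5,5.08],"provenance":"builtin"}
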
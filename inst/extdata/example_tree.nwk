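((Gentiana_demo:0.8,Viola_demo:0.8):0.2,Anaphalis_demo:1);
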
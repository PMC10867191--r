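"species","size_mm","elev_min","elev_max"
"Gentiana_demo",19.5,2900,3300
"Anaphalis_demo",7,2500,3100
"Viola_demo",17.5,3000,3300
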
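species	assembled_size_mb	repeat_content_pct
Ridgeia piscesae	574.9	30.2
Riftia pachyptila	560.7	29.9
Paraescarpia echinospica	1090.9	55.1
Lamellibrachia luymesi	687.7	38.2
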
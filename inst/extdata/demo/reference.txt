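OG00011
OG00012
OG00013
OG00014
OG00015
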
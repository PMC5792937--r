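"species","clade"
"sp01","west"
"sp02","east"
"sp03","east"
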
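((sp01:0.1264722691,sp02:0.1264722691):0.8735277309,sp03:1);
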
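>taxonA
ACGTACGTACGTACGTACGT
>taxonB
ACG---GTACGTACGTACGA
>taxonC
ACG---GTACGTACGTACGA
>taxonD
AC-----TACGTACGTACGT
>taxonE
ACGTACGTACGTACGAACGT
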
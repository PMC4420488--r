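>A1-like.3p
AGATCGGAAGAGCACACGTCT
>A1-like.5p
GUUCAGAGUUCUACAGUCCGACGAUC
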
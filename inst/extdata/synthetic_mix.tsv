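id	concentration
syn0001	1
syn0002	1
syn0003	5
syn0004	1
syn0005	1
syn0006	1
syn0007	5
syn0008	1
syn0009	1
syn0010	1
syn0011	5
syn0012	1
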
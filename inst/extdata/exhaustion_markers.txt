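HAVCR2
PDCD1
CTLA4
CXCL8
LAG3
EOMES
TOX
TIGIT
CD244
NR4A1
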
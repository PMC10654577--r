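IL2
IFNG
PRF1
GZMB
GZMK
GZMA
CD69
CD25
CD38
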
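4cefb7e2c3edf26118fe6915945c652d
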
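file	md5
phenolics_rt.csv	39b340456ae6d6bc1f8b5d558cd85777
phenolics_structures.csv	229ee34e67de12c3fa35a123df6abb71
published_models.json	1ea61376fc0b301a938378a6f33d31cb
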
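0 0.10 0.10 0.90 0.10 0.50 0.90
1 0.20 0.55 0.45 0.55 0.45 0.80 0.20 0.80
0 0.60 0.60 0.85 0.60 0.85 0.85 0.60 0.85
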
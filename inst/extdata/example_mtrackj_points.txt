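TID PID x y frame
1 1 10.0 20.0 1
1 2 12.0 20.0 2
1 3 12.0 23.0 3
2 1 50.0 50.0 1
2 2 50.0 50.0 2
2 3 50.0 50.0 3
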
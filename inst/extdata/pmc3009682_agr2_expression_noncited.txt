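21454516
21281432
20531310
20525379
20025862
19773444
18829536
9831665
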
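# na0 k0 cl0 B0 kv na k cl beta gamma
140 5.8 116 48.2 1.0 33 152 45 0.039 1.5
# pna pk pcl inc ikc inkcc hp kb
0.00382 0.022 0.0091 3E-5 0 0 240 0
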
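# unit-corner tetrahedron, volume 1/6 mm^3
4 3 0 0
1 0 0 0
2 1 0 0
3 0 1 0
4 0 0 1
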
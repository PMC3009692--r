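context	dG
CAACGG	5.5
CCAAGG	3.3
CCACGG	3.7
CCCAGG	3.4
CCGAGG	3.5
CCGCGG	3.6
CCUAGG	3.7
CCUCGG	2.5
CUAAGG	3.6
CUACGG	2.8
CUCAGG	3.7
CUCCGG	2.7
CUGCGG	2.8
CUUAGG	3.5
CUUCGG	3.7
CUUUGG	3.7
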
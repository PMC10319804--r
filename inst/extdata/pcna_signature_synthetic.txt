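gene0001
gene0002
gene0003
gene0004
gene0005
gene0006
gene0007
gene0008
gene0009
gene0010
gene0011
gene0012
gene0013
gene0014
gene0015
gene0016
gene0017
gene0018
gene0019
gene0020
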
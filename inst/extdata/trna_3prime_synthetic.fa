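>tRNA-Met
TGGTTCGAGTCCGAGTCG
>tRNA-Lys
TGGCGCCCAACGTGGGGC
>tRNA-Trp
TGGTAGCTCAGTTGGTAG
>tRNA-Ile
TGGCCCGTTAGCTCAGTT
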
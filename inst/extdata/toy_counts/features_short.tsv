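ENSG00000177455	CD19	Gene Expression
ENSG00000156738	MS4A1	Gene Expression
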
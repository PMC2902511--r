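accession	pattern	anchor_index	description
PS00070	[FYLVA]-x(2)-G-[QE]-C-[LIVMGSTANC]-[AGCN]	6	ALDH cysteine active site (synthetic stand-in; anchor = catalytic Cys)
PS00687	[LIVMFGA]-E-[LIMSTAC]-[GS]-G-[KNLM]-[SADN]-[TAPFV]	2	ALDH glutamic acid active site (synthetic stand-in; anchor = catalytic Glu)
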
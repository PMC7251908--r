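ligand	receptor	class
CD274	PDCD1	checkpoint
PDCD1LG2	PDCD1	checkpoint
CD80	CTLA4	checkpoint
CD86	CTLA4	checkpoint
PVR	TIGIT	checkpoint
HLA-DRA	LAG3	checkpoint
CD274	Pdcd1	checkpoint_pdx
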
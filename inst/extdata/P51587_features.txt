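# Feature track for human BRCA2 (UniProt P51587), plain dialect:
# KIND START END LABEL (1-based inclusive coordinates).
# Compiled from the UniProt positional annotation: the eight BRC repeats
# that mediate RAD51 binding and the checkpoint-kinase phosphorylation
# sites in the carboxy-terminal region.
REPEAT 1002 1036 BRC1
REPEAT 1212 1246 BRC2
REPEAT 1421 1455 BRC3
REPEAT 1517 1551 BRC4
REPEAT 1664 1698 BRC5
REPEAT 1837 1871 BRC6
REPEAT 1971 2005 BRC7
REPEAT 2051 2085 BRC8
MOD_RES 3291 3291 Phosphoserine (CDK)
MOD_RES 3387 3387 Phosphothreonine (CHK1/CHK2)
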
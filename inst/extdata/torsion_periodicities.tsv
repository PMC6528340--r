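# Curated subset of rotatable-bond torsion periodicities.
# Format: SMARTS<TAB>periodicity. First match wins, so specific patterns
# come before generic ones. Patterns are written linearly through the
# rotatable bond: the bond's two atoms must appear as consecutive pattern
# atoms for a record to apply.
O=[CX3][NX3]	2
O=[CX3][OX2][#6]	2
O=[CX3][CX4]	6
[cX3][CX3]=O	2
[NX3][cX3]	2
[OX2][cX3]	2
[cX3]!@[cX3]	2
[CX3]=[CX3][CX3]=[CX3]	2
[cX3][CX4]	6
[CX3]=[CX3][CX4]	6
[CX4][CX4]	3
[CX4][NX3]	3
[CX4][OX2]	3
[CX4][SX2]	3
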
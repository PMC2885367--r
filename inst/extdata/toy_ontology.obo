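format-version: 1.2
ontology: toy

[Term]
id: TOY:0000001
name: biological process

[Term]
id: TOY:0000010
name: metabolic process
is_a: TOY:0000001 ! biological process

[Term]
id: TOY:0000011
name: lipid metabolic process
is_a: TOY:0000010 ! metabolic process

[Term]
id: TOY:0000012
name: amino acid metabolic process
is_a: TOY:0000010 ! metabolic process

[Term]
id: TOY:0000020
name: neural process
is_a: TOY:0000001 ! biological process

[Term]
id: TOY:0000021
name: synaptic transmission
is_a: TOY:0000020 ! neural process

[Term]
id: TOY:0000022
name: axon guidance
is_a: TOY:0000020 ! neural process

[Term]
id: TOY:0000030
name: immune process
is_a: TOY:0000001 ! biological process

[Term]
id: TOY:0000031
name: antigen presentation
is_a: TOY:0000030 ! immune process

[Term]
id: TOY:0000040
name: muscle contraction
is_a: TOY:0000001 ! biological process

[Term]
id: TOY:0000099
name: obsolete process
is_obsolete: true
is_a: TOY:0000001 ! biological process
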
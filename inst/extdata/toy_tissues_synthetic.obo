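format-version: 1.2
remark: Synthetic miniature tissue ontology for examples and tests. The term
remark: set and structure are invented; ids use the TOY namespace.

[Term]
id: TOY:0000001
name: tissues, cell types and enzyme sources

[Term]
id: TOY:0000002
name: animal
is_a: TOY:0000001

[Term]
id: TOY:0000003
name: viscus
is_a: TOY:0000002

[Term]
id: TOY:0000004
name: pancreas
synonym: "pancreatic gland" RELATED []
is_a: TOY:0000003

[Term]
id: TOY:0000005
name: liver
synonym: "hepar" RELATED []
is_a: TOY:0000003

[Term]
id: TOY:0000006
name: nervous system
is_a: TOY:0000002

[Term]
id: TOY:0000007
name: brain
synonym: "encephalon" EXACT []
is_a: TOY:0000006

[Term]
id: TOY:0000008
name: hippocampus
synonym: "Ammon horn" RELATED []
is_a: TOY:0000007

[Term]
id: TOY:0000009
name: hippocampal pyramidal layer
is_a: TOY:0000008

[Term]
id: TOY:0000010
name: ovary
synonym: "ovarium" EXACT []
is_a: TOY:0000003

[Term]
id: TOY:0000011
name: blood
synonym: "peripheral blood" NARROW []
is_a: TOY:0000002

[Term]
id: TOY:0000012
name: lung
is_a: TOY:0000003

[Term]
id: TOY:0000013
name: kidney
synonym: "ren" RELATED []
is_a: TOY:0000003

[Term]
id: TOY:0000014
name: heart
synonym: "cor" RELATED []
is_a: TOY:0000003
is_a: TOY:0000015

[Term]
id: TOY:0000015
name: muscular system
is_a: TOY:0000002

[Term]
id: TOY:0000016
name: cap
is_a: TOY:0000003

[Term]
id: TOY:0000017
name: retired structure
is_obsolete: true
is_a: TOY:0000002
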
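format-version: 1.2
ontology: synthetic miniature phenotype ontology (example data)

[Term]
id: HP:0000001
name: All

[Term]
id: HP:0000118
name: Phenotypic abnormality
is_a: HP:0000001

[Term]
id: HP:0000005
name: Mode of inheritance
is_a: HP:0000001

[Term]
id: HP:0000007
name: Autosomal recessive inheritance
is_a: HP:0000005

[Term]
id: HP:0012638
name: Abnormal nervous system physiology
is_a: HP:0000118

[Term]
id: HP:0001250
name: Seizure
is_a: HP:0012638

[Term]
id: HP:0002123
name: Generalized myoclonic seizure
is_a: HP:0001250

[Term]
id: HP:0001251
name: Ataxia
is_a: HP:0012638

[Term]
id: HP:0009999
name: Retired term
is_obsolete: true
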
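format-version: 1.2
ontology: mini-chebi

[Term]
id: CHEBI:15318
name: xanthine
namespace: chebi_ontology
synonym: "3,7-dihydro-1H-purine-2,6-dione" EXACT []
is_a: FIX:C019

[Term]
id: CHEBI:16227
name: pyridine
namespace: chebi_ontology
is_a: FIX:C001

[Term]
id: CHEBI:16646
name: carbohydrate
namespace: chebi_ontology
is_a: FIX:C001

[Term]
id: CHEBI:26421
name: pyridines
namespace: chebi_ontology
is_a: FIX:C001

[Term]
id: CHEBI:30772
name: butyric acid
namespace: chebi_ontology
synonym: "butanoic acid" EXACT []
is_a: FIX:C007

[Term]
id: FIX:C001
name: chemical entity
namespace: chebi_ontology

[Term]
id: FIX:C002
name: monosaccharide
namespace: chebi_ontology
is_a: CHEBI:16646

[Term]
id: FIX:C003
name: hexose
namespace: chebi_ontology
is_a: FIX:C002

[Term]
id: FIX:C004
name: glucose
namespace: chebi_ontology
is_a: FIX:C003

[Term]
id: FIX:C005
name: hexose phosphate
namespace: chebi_ontology
is_a: CHEBI:16646

[Term]
id: FIX:C006
name: glucose-6-phosphate
namespace: chebi_ontology
synonym: "D-glucose 6-phosphate" EXACT []
is_a: FIX:C005

[Term]
id: FIX:C007
name: carboxylic acid
namespace: chebi_ontology
is_a: FIX:C001

[Term]
id: FIX:C008
name: tricarboxylic acid
namespace: chebi_ontology
is_a: FIX:C007

[Term]
id: FIX:C009
name: nitrilotriacetic acid
namespace: chebi_ontology
is_a: FIX:C008

[Term]
id: FIX:C010
name: nitrilotriacetate
namespace: chebi_ontology
is_a: FIX:C011
relationship: is_conjugate_base_of FIX:C009

[Term]
id: FIX:C011
name: carboxylic acid anion
namespace: chebi_ontology
is_a: FIX:C001

[Term]
id: FIX:C012
name: citric acid
namespace: chebi_ontology
is_a: FIX:C008
relationship: is_conjugate_acid_of FIX:C013

[Term]
id: FIX:C013
name: citrate(1-)
namespace: chebi_ontology
is_a: FIX:C011
relationship: is_conjugate_acid_of FIX:C014
relationship: is_conjugate_base_of FIX:C012

[Term]
id: FIX:C014
name: citrate(2-)
namespace: chebi_ontology
is_a: FIX:C011
relationship: is_conjugate_acid_of FIX:C015

[Term]
id: FIX:C015
name: citrate(3-)
namespace: chebi_ontology
is_a: FIX:C011

[Term]
id: FIX:C016
name: phenol
namespace: chebi_ontology
is_a: FIX:C001

[Term]
id: FIX:C017
name: phenols
namespace: chebi_ontology
is_a: FIX:C001

[Term]
id: FIX:C018
name: benzene
namespace: chebi_ontology
is_a: FIX:C001

[Term]
id: FIX:C019
name: purine
namespace: chebi_ontology
is_a: FIX:C001

[Term]
id: FIX:C020
name: oxime
namespace: chebi_ontology
is_a: FIX:C001

[Term]
id: FIX:C021
name: alkaloid
namespace: chebi_ontology
is_a: FIX:C001

[Term]
id: FIX:C022
name: retired chemical
namespace: chebi_ontology
is_obsolete: true

[Typedef]
id: has_functional_parent
name: has_functional_parent

[Typedef]
id: has_role
name: has_role

[Typedef]
id: is_conjugate_acid_of
name: is_conjugate_acid_of

[Typedef]
id: is_conjugate_base_of
name: is_conjugate_base_of

[Typedef]
id: is_tautomer_of
name: is_tautomer_of
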
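format-version: 1.2
ontology: mini-go

[Term]
id: FIX:G001
name: glucose-6-phosphate transport
namespace: biological_process
is_a: FIX:G002
is_a: FIX:G003

[Term]
id: FIX:G002
name: glucose transport
namespace: biological_process
is_a: FIX:G004

[Term]
id: FIX:G003
name: hexose phosphate transport
namespace: biological_process
is_a: FIX:G004

[Term]
id: FIX:G004
name: carbohydrate transport
namespace: biological_process
is_a: GO:0006810

[Term]
id: FIX:G005
name: glucose transporter activity
namespace: biological_process
is_a: GO:0005215

[Term]
id: FIX:G006
name: hexose phosphate transporter activity
namespace: biological_process
is_a: GO:0005215

[Term]
id: FIX:G007
name: glucose-6-phosphate transporter activity
namespace: biological_process
is_a: FIX:G006

[Term]
id: FIX:G008
name: carboxylic acid metabolic process
namespace: biological_process
is_a: GO:0008152

[Term]
id: FIX:G009
name: tricarboxylic acid metabolic process
namespace: biological_process
is_a: FIX:G008

[Term]
id: FIX:G010
name: nitrilotriacetate metabolic process
namespace: biological_process
is_a: FIX:G009

[Term]
id: FIX:G011
name: aldoxime metabolic process
namespace: biological_process
is_a: GO:0008152

[Term]
id: FIX:G012
name: pyridine catabolic process
namespace: biological_process
is_a: GO:0009056

[Term]
id: FIX:G013
name: butanoic acid metabolic process
namespace: biological_process
is_a: GO:0008152

[Term]
id: FIX:G014
name: purine biosynthetic process
namespace: biological_process
is_a: GO:0009058

[Term]
id: FIX:G015
name: alkaloid biosynthetic process
namespace: biological_process
is_a: GO:0009058

[Term]
id: GO:0005215
name: transporter activity
namespace: biological_process

[Term]
id: GO:0005488
name: binding
namespace: biological_process

[Term]
id: GO:0005975
name: carbohydrate metabolic process
namespace: biological_process
is_a: GO:0008152

[Term]
id: GO:0006810
name: transport
namespace: biological_process

[Term]
id: GO:0008152
name: metabolic process
namespace: biological_process

[Term]
id: GO:0009056
name: catabolic process
namespace: biological_process
is_a: GO:0008152

[Term]
id: GO:0009058
name: biosynthetic process
namespace: biological_process
is_a: GO:0008152

[Term]
id: GO:0018910
name: benzene metabolic process
namespace: biological_process
is_a: GO:0008152

[Term]
id: GO:0018958
name: phenol metabolic process
namespace: biological_process
is_a: GO:0008152

[Term]
id: GO:0030246
name: carbohydrate binding
namespace: biological_process
is_a: GO:0005488

[Term]
id: GO:0046903
name: secretion
namespace: biological_process
is_a: GO:0006810

[Term]
id: GO:0048878
name: chemical homeostasis
namespace: biological_process

[Term]
id: GO:0050896
name: response to stimulus
namespace: biological_process

[Typedef]
id: has_input
name: has_input

[Typedef]
id: has_output
name: has_output

[Typedef]
id: has_participant
name: has_participant

[Typedef]
id: regulates_levels_of
name: regulates_levels_of

[Typedef]
id: transports
name: transports
is_a: transports_or_maintains_localization_of

[Typedef]
id: transports_or_maintains_localization_of
name: transports_or_maintains_localization_of
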
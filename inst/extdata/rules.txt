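# Default classification rules.
# One rule per line:  TI_PATTERN [| ST=PATTERN] [| TT=PATTERN] -> CATEGORY
# Patterns are case-insensitive globs ('*' = any run, '?' = one character)
# over the interaction-type token (TI), optionally gated on the source (ST)
# and target (TT) entity-type tokens. First matching rule wins; records that
# match no rule are treated as unspecified protein-protein interactions.

phosphorylation | ST=kinase -> KINASE_PHOSPHORYLATION
phosphorylation -> KINASE_PHOSPHORYLATION
dephosphorylation -> DEPHOSPHORYLATION

guanine?nucleotide?exchange -> GUANINE_NUCLEOTIDE_EXCHANGE
gef -> GUANINE_NUCLEOTIDE_EXCHANGE
gap?reaction -> GAP_REACTION
gap -> GAP_REACTION
gtpase?activation -> GAP_REACTION

deubiquitination -> DEUBIQUITINATION
ubiquitination -> UBIQUITINATION
sumoylation -> SUMOYLATION

plc?cleavage -> PLC_CLEAVAGE
cysteine?cleavage -> CYSTEINE_CLEAVAGE
inactivating?cleavage -> INACTIVATING_CLEAVAGE
activating?cleavage -> ACTIVATING_CLEAVAGE
cleavage -> INACTIVATING_CLEAVAGE

tf?promoter?binding -> TF_PROMOTER_BINDING
promoter?binding -> TF_PROMOTER_BINDING
binding | ST=transcription?factor -> TF_PROMOTER_BINDING
binding -> BINDING
complex?formation -> BINDING

transcription -> TRANSCRIPTION
expression | TT=gene -> TRANSCRIPTION

pp -> PROTEIN_PROTEIN_INTERACTION
interaction -> PROTEIN_PROTEIN_INTERACTION
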
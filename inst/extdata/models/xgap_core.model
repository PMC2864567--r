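# Built-in XGAP object model.
#
# Core experiment types (Investigation, Protocol, ProtocolApplication,
# Data, DimensionElement) follow the FuGE pattern; Trait and Subject
# variants extend DimensionElement. Matrices (sets of DataElements) are
# declared by Data records and stored as separate matrix files; a matrix
# cell is not an entity here.
#
# Names are the business keys of the tab format; the numeric primary key
# (molgenisid) is added when the relational schema is derived.

entity Investigation
  name: string, required
  description: text

entity Protocol
  name: string, required
  investigation_name: xref -> Investigation
  description: text

entity ProtocolApplication
  name: string, required
  investigation_name: xref -> Investigation
  protocol: xref -> Protocol
  inputdata: mref -> Data
  outputdata: mref -> Data

entity Data
  name: string, required
  investigation_name: xref -> Investigation
  rowtype: string, required    # concrete DimensionElement variant of the matrix rows
  coltype: string, required    # concrete DimensionElement variant of the matrix columns
  valuetype: string, required  # decimal or text

entity DimensionElement
  name: string, required
  type: string                 # free-text descriptor
  investigation_name: xref -> Investigation

entity Trait extends DimensionElement

entity Subject extends DimensionElement

interface Locus
  chromosome: text
  bp_start: int                # 1-based, inclusive
  bp_end: int                  # 1-based, inclusive
  cm: decimal                  # genetic map position in centimorgan

entity Marker extends Trait implements Locus

entity Probe extends Trait implements Locus
  sequence: text

entity Gene extends Trait implements Locus

entity Metabolite extends Trait
  mass: decimal                # monoisotopic mass in Da
  formula: text
  structure: text              # free text; SMILES or InChI welcome

entity Sample extends Subject
  tissue: text
  individual: xref -> Individual

entity PairedSample extends Sample
  cy3_subject: xref -> Subject, required
  cy5_subject: xref -> Subject, required

entity Individual extends Subject
  mother: xref -> Individual
  father: xref -> Individual
  strain: xref -> Strain

entity Strain extends Subject
  parent_strains: mref -> Strain
  breeding_method: text

entity InbredStrain extends Strain
  inbreeding_type: text

# Annotation types: free additions attachable to DimensionElement,
# Investigation, Protocol, ProtocolApplication and Data records, addressed
# by (target_entity, target_name).

entity OntologyTerm
  name: string, required
  investigation_name: xref -> Investigation
  target_entity: string, required
  target_name: string, required
  term: string
  accession: string
  ontology: string

entity DatabaseEntry
  name: string, required
  investigation_name: xref -> Investigation
  target_entity: string, required
  target_name: string, required
  database_name: string
  accession: string

entity BibliographicReference
  name: string, required
  investigation_name: xref -> Investigation
  target_entity: string, required
  target_name: string, required
  citation: text
  pubmed_id: string

entity URI
  name: string, required
  investigation_name: xref -> Investigation
  target_entity: string, required
  target_name: string, required
  uri: string

entity FileAttachment
  name: string, required
  investigation_name: xref -> Investigation
  target_entity: string, required
  target_name: string, required
  path: string                 # relative path, typically under original/

entity Description
  name: string, required
  investigation_name: xref -> Investigation
  target_entity: string, required
  target_name: string, required
  description: text

# Protocol detail types.

entity Action
  name: string, required
  investigation_name: xref -> Investigation
  protocol: xref -> Protocol
  description: text

entity Software
  name: string, required
  investigation_name: xref -> Investigation
  protocol: xref -> Protocol
  description: text

entity Equipment
  name: string, required
  investigation_name: xref -> Investigation
  protocol: xref -> Protocol
  description: text

entity Parameter
  name: string, required
  investigation_name: xref -> Investigation
  protocol: xref -> Protocol
  description: text

entity ParameterValue
  name: string, required
  investigation_name: xref -> Investigation
  parameter: xref -> Parameter
  protocolapplication: xref -> ProtocolApplication
  value: text
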
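# Curated transcription of the dependency map behind the export of a
# cell-based assay and its experimental data: 30 scientific concepts across
# the genomic, proteomic, molecular-entity, disease/anatomy, assay, ontology
# and scientific-community ecosystems, layered over 9 dependency levels.
# `flags` are annotation flags: "publications" adds a related edge to the
# publication concept, "evidence_ontology" to the evidence-ontology concept.
# Transcription notes: arrows between densely packed ontology boxes overlap
# in the source figure; where a related arrow's origin was ambiguous it was
# resolved to the nearest ontology box and recorded here rather than
# silently dropped (external_identifier edges for gene and small_molecule).
organism:
  ecosystem: genomic
  unicity_key: [tax_id]
publication:
  ecosystem: community
  unicity_key: [pmid]
evidence_ontology:
  ecosystem: ontology
  unicity_key: [eco_id]
gene_ontology:
  ecosystem: ontology
  unicity_key: [go_id]
disease_ontology:
  ecosystem: ontology
  unicity_key: [doid]
anatomy_ontology:
  ecosystem: ontology
  unicity_key: [uberon_id]
chemical_ontology:
  ecosystem: ontology
  unicity_key: [chebi_id]
unit_ontology:
  ecosystem: ontology
  unicity_key: [uo_id]
external_identifier:
  ecosystem: community
  unicity_key: [registry, accession]
assay_format:
  ecosystem: assay
  unicity_key: [format_id]
detection_technology:
  ecosystem: assay
  unicity_key: [technology_id]
gene:
  ecosystem: genomic
  critical: [organism]
  related: [external_identifier]
  unicity_key: [symbol]
  flags: [publications]
genome_assembly:
  ecosystem: genomic
  critical: [organism]
  unicity_key: [assembly_id]
chromosome:
  ecosystem: genomic
  critical: [organism]
  unicity_key: [name]
tissue:
  ecosystem: disease_anatomy
  critical: [organism, anatomy_ontology]
  unicity_key: [tissue_id]
cell_type:
  ecosystem: disease_anatomy
  critical: [anatomy_ontology]
  unicity_key: [cell_type_id]
disease:
  ecosystem: disease_anatomy
  critical: [disease_ontology]
  unicity_key: [disease_id]
  flags: [publications]
molecular_entity:
  ecosystem: molecular_entity
  critical: [chemical_ontology]
  unicity_key: [entity_id]
compound_structure:
  ecosystem: molecular_entity
  critical: [chemical_ontology]
  unicity_key: [inchi_key]
assay_protocol:
  ecosystem: assay
  critical: [assay_format]
  unicity_key: [protocol_id]
genomic_sequence:
  ecosystem: genomic
  critical: [genome_assembly, chromosome]
  unicity_key: [chromosome, assembly_id]
cell_line:
  ecosystem: disease_anatomy
  critical: [tissue, cell_type]
  unicity_key: [cell_line_id]
  flags: [publications]
small_molecule:
  ecosystem: molecular_entity
  critical: [molecular_entity, compound_structure]
  related: [external_identifier]
  unicity_key: [compound_id]
  flags: [publications]
transcript:
  ecosystem: genomic
  critical: [gene, genomic_sequence]
  unicity_key: [transcript_id]
protein:
  ecosystem: proteomic
  critical: [transcript, organism]
  related: [gene_ontology]
  unicity_key: [protein_id]
  flags: [publications, evidence_ontology]
sirna:
  ecosystem: molecular_entity
  critical: [molecular_entity, transcript]
  unicity_key: [sirna_id]
protein_isoform:
  ecosystem: proteomic
  critical: [protein]
  unicity_key: [isoform_id]
macromolecular_target:
  ecosystem: proteomic
  critical: [protein_isoform]
  unicity_key: [target_id]
  flags: [publications]
cell_based_assay:
  ecosystem: assay
  critical: [macromolecular_target, cell_line, assay_protocol, detection_technology, disease]
  unicity_key: [assay_id]
  flags: [publications]
experimental_data:
  ecosystem: assay
  critical: [cell_based_assay, small_molecule, sirna, unit_ontology]
  unicity_key: [result_id]
  flags: [publications, evidence_ontology]
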
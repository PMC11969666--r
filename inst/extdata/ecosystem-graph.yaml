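# Concept graph for the synthetic multi-provider toy ecosystem: the minimal
# set of concepts needed to load taxonomy, two overlapping gene providers, a
# chromosome with transcript/CDS annotation, variants, proteins, assays and
# experimental results into one warehouse.
organism:
  ecosystem: genomic
  unicity_key: [tax_id]
gene:
  ecosystem: genomic
  critical: [organism]
  unicity_key: [symbol]
chromosome:
  ecosystem: genomic
  critical: [organism]
  unicity_key: [name]
transcript:
  ecosystem: genomic
  critical: [gene, chromosome]
  unicity_key: [transcript_id]
variant:
  ecosystem: genomic
  critical: [chromosome]
  unicity_key: [chrom, pos, ref, alt]
protein:
  ecosystem: proteomic
  critical: [transcript]
  unicity_key: [protein_id]
assay:
  ecosystem: assay
  critical: [protein]
  unicity_key: [assay_id]
experimental_result:
  ecosystem: assay
  critical: [assay]
  unicity_key: [result_id]
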
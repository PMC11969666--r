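# The genomic dependency chain: chromosome-level DNA sequence requires the
# organism first (root, L1), then the genome assembly and the chromosome
# record (both L2), making the genomic sequence the third dependency layer.
organism:
  ecosystem: genomic
  unicity_key: [tax_id]
genome_assembly:
  ecosystem: genomic
  critical: [organism]
  unicity_key: [assembly_id]
chromosome:
  ecosystem: genomic
  critical: [organism]
  unicity_key: [name]
genomic_sequence:
  ecosystem: genomic
  critical: [genome_assembly, chromosome]
  unicity_key: [chromosome, assembly_id]
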
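# Synthetic gene annotation for the example amplicon region.
# The CDS placement and sequence are fabricated test fixtures, not a genome lookup.
chrom: chrXV
start: 780367
end: 782084
cds_start: 780867
cds_end: 781502
strand: '+'
cds_fasta: synthetic_cds.fasta
conserved: [29, 35, 38, 63, 141]
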
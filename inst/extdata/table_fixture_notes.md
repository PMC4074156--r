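# Notes on the bundled catalog-table fixtures

- `table1_or.csv` (45 rows) and `table2_ir.csv` (13 rows) transcribe the
  published cotton-aphid OR/IR catalog summaries as printed. Status strings
  were mapped to the package enum: "Complete ORF" -> complete;
  "5' exon lost" and "5' lost" -> partial_N; "3' exon lost" -> partial_C;
  "5',3' exon lost" -> partial_NC; "Internal exon lost" -> partial_M;
  "Pseudogene" -> pseudogene. IR percent identities are stored as fractions.
- Known internal discrepancy of the source publication, transcribed as
  printed and deliberately not "fixed": the running text counts 22 complete
  OR genes, but only 20 rows of the OR table read "Complete ORF" (and the
  text's 14 incomplete genes correspond to 16 non-complete, non-pseudogene
  rows). Consequently the text's "average identity of intact genes, 64.08%"
  does not equal the mean over the 20 complete rows (0.644) and is not used
  as a checked statistic anywhere in this package.
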
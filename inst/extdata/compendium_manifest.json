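{
  "datasets": {
    "GEO": 21592,
    "TCGA": 10817,
    "CCLE": 1067,
    "GDSC": 1018
  },
  "gene_set_collections": {
    "BioCarta": 7,
    "KEGG": 64,
    "GO": 508,
    "Reactome": 29
  },
  "sample_classes": {
    "cancer_biopsy": 28200,
    "non_cancer_tissue": 4209,
    "cell_line": 2085
  },
  "cell_line_datasets": ["CCLE", "GDSC"]
}
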
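{
  "kind": "object",
  "required": ["parameters", "karyotype", "fish", "expression", "metrics"],
  "properties": {
    "parameters": { "kind": "object", "required": ["seed"] },
    "karyotype": {
      "kind": "object",
      "required": ["replicates", "recurrent"],
      "properties": {
        "replicates": {
          "kind": "table",
          "columns": ["replicate_id", "condition", "iscn"]
        },
        "recurrent": {
          "kind": "table",
          "columns": ["aberration", "n_karyotypes", "n_karyotypes_multiple", "total_copies"]
        }
      }
    },
    "fish": {
      "kind": "object",
      "required": ["calls", "truth"],
      "properties": {
        "calls": {
          "kind": "table",
          "columns": ["sample_id", "probe_set", "n_cells_scored", "normal",
                      "gain_or_break", "fusion_positive", "uninformative",
                      "informative", "call"]
        },
        "truth": { "kind": "table", "columns": ["sample_id", "fusion_truth"] }
      }
    },
    "expression": {
      "kind": "object",
      "required": ["candidates", "truth"],
      "properties": {
        "candidates": {
          "kind": "table",
          "columns": ["window", "gene_id", "chrom", "start", "end",
                      "fc", "log10fc", "p", "passes"]
        },
        "truth": { "kind": "table", "columns": ["gene_id", "fold_change", "window"] }
      }
    },
    "metrics": {
      "kind": "object",
      "required": ["expression_sensitivity", "expression_sign_agreement",
                   "karyotype_translocation_replicates"]
    }
  }
}
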
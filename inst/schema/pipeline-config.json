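{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "myopiaGxE pipeline configuration",
  "type": "object",
  "required": ["weights", "genotypes", "phenotypes", "out_dir"],
  "properties": {
    "weights": {"type": "string", "description": "SNP weight TSV path"},
    "genotypes": {"type": "string", "description": "VCF or dosage TSV path"},
    "phenotypes": {"type": "string", "description": "phenotype CSV path"},
    "out_dir": {"type": "string", "description": "report output directory"},
    "scheme": {"enum": ["hyperopia_control", "emmetropia_control"],
               "default": "hyperopia_control"},
    "cut_points": {"type": "array", "items": {"type": "number"},
                   "minItems": 2, "maxItems": 2, "default": [2.25, 3.0]},
    "collapse": {"enum": ["corners", "dichotomized"], "default": "corners"},
    "covariates": {"type": "array", "items": {"type": "string"},
                   "default": ["age", "sex_male"]},
    "per_sd": {"type": "boolean", "default": false},
    "impute_mean": {"type": "boolean", "default": false},
    "seed": {"type": ["integer", "null"],
             "description": "logged only; the pipeline is deterministic"}
  }
}
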
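{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "seedkit results document",
  "type": "object",
  "required": ["tool", "version", "config", "normalization", "mode",
               "engine", "solutions", "termination"],
  "properties": {
    "tool": {"type": "string", "const": "seedkit"},
    "version": {"type": "string"},
    "config": {"type": "object"},
    "normalization": {
      "type": "object",
      "required": ["split", "reversed", "deleted", "blocked_imports",
                   "kept_imports"],
      "properties": {
        "split": {"type": "integer", "minimum": 0},
        "reversed": {"type": "integer", "minimum": 0},
        "deleted": {"type": "integer", "minimum": 0},
        "blocked_imports": {"type": "integer", "minimum": 0},
        "kept_imports": {"type": "integer", "minimum": 0}
      }
    },
    "mode": {"enum": ["target", "full_network"]},
    "engine": {"enum": ["reasoning", "hybrid_filter", "hybrid_gc",
                        "hybrid_gc_div", "full_hybrid"]},
    "no_accumulation": {"type": "boolean"},
    "candidates": {"type": "integer", "minimum": 0},
    "forced_seeds": {"type": "array", "items": {"type": "string"}},
    "solutions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["seeds", "ne_valid", "minimality"],
        "properties": {
          "seeds": {"type": "array", "items": {"type": "string"},
                    "minItems": 0},
          "ne_valid": {"type": "boolean"},
          "no_accumulation_valid": {"type": ["boolean", "null"]},
          "fba_flux": {"type": ["number", "null"]},
          "fba_valid": {"type": "boolean"},
          "minimality": {"enum": ["ne_subset_minimal",
                                  "hybrid_subset_minimal",
                                  "cardinality_minimal"]}
        }
      }
    },
    "statistics": {
      "type": ["object", "null"],
      "properties": {
        "n_solutions": {"type": "integer", "minimum": 1},
        "sizes": {"type": "array", "items": {"type": "integer"}},
        "union_size": {"type": "integer", "minimum": 0},
        "union_size_dereplicated": {"type": "integer", "minimum": 0},
        "n_imported": {"type": "integer", "minimum": 0},
        "n_internal": {"type": "integer", "minimum": 0}
      }
    },
    "termination": {"enum": ["exhausted", "solution_limit", "timeout",
                             "unsatisfiable"]}
  }
}
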
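{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "substructure annotation result",
  "type": "object",
  "required": ["molecules"],
  "properties": {
    "molecules": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "smiles", "error", "matches"],
        "properties": {
          "name": {"type": "string"},
          "smiles": {"type": "string"},
          "error": {"type": ["string", "null"]},
          "matches": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["pattern_id", "pattern_name", "category",
                           "atom_indices", "bonds", "overshadowed",
                           "suppression_reason", "suppressed_by"],
              "properties": {
                "pattern_id": {"type": "string"},
                "pattern_name": {"type": "string"},
                "category": {"enum": ["functional_group", "cyclic", "biological"]},
                "atom_indices": {
                  "type": "array", "minItems": 1,
                  "items": {"type": "integer", "minimum": 0}
                },
                "bonds": {
                  "type": "array",
                  "items": {
                    "type": "array", "minItems": 2, "maxItems": 2,
                    "items": {"type": "integer", "minimum": 0}
                  }
                },
                "overshadowed": {"type": "boolean"},
                "suppression_reason": {
                  "enum": ["none", "match_containment", "fewer_bonds", "hierarchy"]
                },
                "suppressed_by": {
                  "type": "array", "items": {"type": "string"}
                }
              }
            }
          }
        }
      }
    }
  }
}
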
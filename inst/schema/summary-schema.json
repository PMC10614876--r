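{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "prophagr dataset summary",
  "type": "object",
  "required": ["schema_version", "genomes", "queries"],
  "properties": {
    "schema_version": {"type": "string"},
    "genomes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["target_id", "integrations"],
        "properties": {
          "target_id": {"type": "string"},
          "integrations": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["id", "phage", "start", "end", "strand",
                           "full_length", "fragments"],
              "properties": {
                "id": {"type": "string"},
                "phage": {"type": "string"},
                "start": {"type": "integer", "minimum": 1},
                "end": {"type": "integer", "minimum": 1},
                "strand": {"enum": ["+", "-"]},
                "full_length": {"type": "boolean"},
                "query_coverage_nt": {"type": "integer", "minimum": 1},
                "fragments": {
                  "type": "array",
                  "minItems": 1,
                  "items": {
                    "type": "object",
                    "required": ["query_start", "query_end",
                                 "target_start", "target_end",
                                 "evalue", "score"],
                    "properties": {
                      "query_start": {"type": "integer", "minimum": 1},
                      "query_end": {"type": "integer", "minimum": 1},
                      "target_start": {"type": "integer", "minimum": 1},
                      "target_end": {"type": "integer", "minimum": 1},
                      "evalue": {"type": "number", "minimum": 0},
                      "score": {"type": "number"}
                    }
                  }
                }
              }
            }
          }
        }
      }
    },
    "queries": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["query_id", "length", "counts", "integrations"],
        "properties": {
          "query_id": {"type": "string"},
          "length": {"type": "integer", "minimum": 1},
          "counts": {
            "type": "array",
            "items": {"type": "integer", "minimum": 0}
          },
          "integrations": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["id", "target", "query_start", "query_end"],
              "properties": {
                "id": {"type": "string"},
                "target": {"type": "string"},
                "query_start": {"type": "integer", "minimum": 1},
                "query_end": {"type": "integer", "minimum": 1},
                "full_length": {"type": "boolean"}
              }
            }
          }
        }
      }
    }
  }
}
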
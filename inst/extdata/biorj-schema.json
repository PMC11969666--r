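{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "biorj-1.0.schema.json",
  "title": "BIORJ dependency-closure exchange document, format 1.0",
  "type": "object",
  "required": ["format_version", "generator", "source_versions", "blocks"],
  "properties": {
    "format_version": {"const": "1.0"},
    "generator": {
      "type": "object",
      "required": ["instance", "schema_version", "created"],
      "properties": {
        "instance": {"type": "string"},
        "schema_version": {"type": "string"},
        "created": {"type": "string"}
      }
    },
    "source_versions": {
      "type": "array",
      "description": "Exactly the (source, version) pairs appearing in record provenance, deduplicated.",
      "items": {
        "type": "object",
        "required": ["source", "version"],
        "properties": {
          "source": {"type": "string"},
          "version": {"type": "string"}
        }
      }
    },
    "blocks": {
      "type": "array",
      "description": "Concept blocks in topological order: a block's concept appears after all of its critical-parent concepts present in the document.",
      "items": {
        "type": "object",
        "required": ["concept", "records"],
        "properties": {
          "concept": {"type": "string"},
          "records": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["local_id", "key_values", "attributes", "parent_refs", "provenance"],
              "properties": {
                "local_id": {"type": "string", "description": "Unique within the document; store surrogate ids never leak."},
                "key_values": {"type": "object", "additionalProperties": {"type": "string"}},
                "attributes": {
                  "type": "array",
                  "items": {
                    "type": "object",
                    "required": ["source", "field", "value"],
                    "properties": {
                      "source": {"type": "string"},
                      "field": {"type": "string"},
                      "value": {"type": "string"}
                    }
                  }
                },
                "parent_refs": {
                  "type": "object",
                  "description": "Dependency name -> local_id of a record in the same or an earlier block.",
                  "additionalProperties": {"type": "string"}
                },
                "provenance": {
                  "type": "array",
                  "items": {
                    "type": "object",
                    "required": ["source", "version"],
                    "properties": {
                      "source": {"type": "string"},
                      "version": {"type": "string"}
                    }
                  }
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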
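{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Flat tensor-graph dialect",
  "description": "Single-assignment tensor graph using the core operator names and semantics: named inputs, an ordered op list (references precede use, each value name produced once), and the output names.",
  "type": "object",
  "properties": {
    "inputs": {
      "type": "object",
      "patternProperties": {
        "^[A-Za-z_][A-Za-z0-9_]*$": {
          "type": "object",
          "properties": {
            "shape": { "type": "array" },
            "value": { "type": ["number", "array"] }
          }
        }
      }
    },
    "ops": {
      "type": "array",
      "items": {
        "type": "object",
        "properties": {
          "op": { "type": "string" },
          "inputs": { "type": "array", "items": { "type": "string" } },
          "output": { "type": "string" },
          "attributes": { "type": "object" }
        },
        "required": ["op", "inputs", "output"]
      }
    },
    "outputs": { "type": "array", "items": { "type": "string" } }
  },
  "required": ["inputs", "ops", "outputs"]
}
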
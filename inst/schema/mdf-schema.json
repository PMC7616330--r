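{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Model Description Format document",
  "description": "A serialized computational-graph model: one top-level entry keyed by the model id, holding format metadata and a map of graphs. Collections are maps keyed by id; declaration order is the key order. Numeric values are scalars or (nested) arrays of numbers; in JSON, non-finite doubles appear as the strings \"NaN\", \"Infinity\", \"-Infinity\".",
  "type": "object",
  "minProperties": 1,
  "maxProperties": 1,
  "patternProperties": {
    "^[A-Za-z_][A-Za-z0-9_]*$": {
      "type": "object",
      "properties": {
        "format": { "type": "string" },
        "graphs": {
          "type": "object",
          "patternProperties": {
            "^[A-Za-z_][A-Za-z0-9_]*$": { "$ref": "#/definitions/graph" }
          }
        },
        "metadata": { "type": "object" }
      },
      "required": ["format", "graphs"]
    }
  },
  "definitions": {
    "value": {
      "description": "numeric scalar, nested numeric array, or a non-finite marker string",
      "type": ["number", "array", "string"]
    },
    "expression": { "type": "string" },
    "graph": {
      "type": "object",
      "properties": {
        "nodes": {
          "type": "object",
          "patternProperties": {
            "^[A-Za-z_][A-Za-z0-9_]*(\\.[A-Za-z_][A-Za-z0-9_]*)*$": {
              "$ref": "#/definitions/node"
            }
          }
        },
        "edges": {
          "type": "object",
          "patternProperties": {
            "^[A-Za-z_][A-Za-z0-9_]*(\\.[A-Za-z_][A-Za-z0-9_]*)*$": {
              "$ref": "#/definitions/edge"
            }
          }
        },
        "conditions": { "$ref": "#/definitions/condition_set" },
        "metadata": { "type": "object" }
      },
      "required": ["nodes", "edges"]
    },
    "node": {
      "type": "object",
      "properties": {
        "input_ports": {
          "type": "object",
          "patternProperties": {
            "^[A-Za-z_][A-Za-z0-9_]*$": {
              "type": "object",
              "properties": {
                "shape": { "type": "array" },
                "reduce": { "enum": ["error", "sum"] }
              }
            }
          }
        },
        "parameters": {
          "type": "object",
          "patternProperties": {
            "^[A-Za-z_][A-Za-z0-9_]*$": {
              "type": "object",
              "properties": {
                "value": { "$ref": "#/definitions/value" },
                "default_initial_value": { "$ref": "#/definitions/value" },
                "time_derivative": { "$ref": "#/definitions/expression" }
              }
            }
          }
        },
        "functions": {
          "type": "object",
          "patternProperties": {
            "^[A-Za-z_][A-Za-z0-9_]*$": {
              "type": "object",
              "properties": {
                "function": { "type": "string" },
                "args": { "type": "object" }
              },
              "required": ["function"]
            }
          }
        },
        "output_ports": {
          "type": "object",
          "patternProperties": {
            "^[A-Za-z_][A-Za-z0-9_]*$": {
              "type": "object",
              "properties": {
                "value": { "$ref": "#/definitions/expression" },
                "default_initial_value": { "$ref": "#/definitions/value" }
              },
              "required": ["value"]
            }
          }
        },
        "subgraph": {
          "type": "object",
          "minProperties": 1,
          "maxProperties": 1,
          "patternProperties": {
            "^[A-Za-z_][A-Za-z0-9_]*$": { "$ref": "#/definitions/graph" }
          }
        },
        "metadata": { "type": "object" }
      }
    },
    "edge": {
      "type": "object",
      "properties": {
        "sender": { "type": "string" },
        "sender_port": { "type": "string" },
        "receiver": { "type": "string" },
        "receiver_port": { "type": "string" },
        "weight": { "type": "number" }
      },
      "required": ["sender", "sender_port", "receiver", "receiver_port"]
    },
    "condition": {
      "type": "object",
      "properties": {
        "type": {
          "enum": ["always", "never", "every_n_calls", "after_n_calls",
                   "before_n_calls", "threshold", "time_interval",
                   "and", "or", "not", "all_have_run"]
        },
        "args": { "type": "object" }
      },
      "required": ["type", "args"]
    },
    "condition_set": {
      "type": "object",
      "properties": {
        "node_specific": {
          "type": "object",
          "patternProperties": {
            "^[A-Za-z_][A-Za-z0-9_]*(\\.[A-Za-z_][A-Za-z0-9_]*)*$": {
              "$ref": "#/definitions/condition"
            }
          }
        },
        "termination": { "$ref": "#/definitions/condition" }
      }
    }
  }
}
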
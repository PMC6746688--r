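{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Landmark annotation of one or two chest photographs",
  "type": "object",
  "required": ["schema_version", "primary"],
  "properties": {
    "schema_version": {"const": "1.0"},
    "subject": {
      "type": "object",
      "properties": {
        "id": {"type": ["string", "null"]},
        "sex_type": {"enum": ["female", "male", null]},
        "notes": {"type": ["string", "null"]}
      }
    },
    "primary": {"$ref": "#/$defs/photo_block"},
    "secondary": {"$ref": "#/$defs/photo_block"}
  },
  "$defs": {
    "point": {
      "type": "object",
      "required": ["x", "y"],
      "properties": {
        "x": {"type": "number"},
        "y": {"type": "number"}
      }
    },
    "photo_block": {
      "type": "object",
      "required": ["photo_id", "calibration", "landmarks"],
      "properties": {
        "photo_id": {"type": "string"},
        "image_path": {"type": ["string", "null"]},
        "image_size": {
          "type": ["array", "null"],
          "items": {"type": "number"},
          "minItems": 2,
          "maxItems": 2
        },
        "calibration": {
          "type": "object",
          "required": ["endpoint_a", "endpoint_b", "known_length_cm"],
          "properties": {
            "endpoint_a": {"$ref": "#/$defs/point"},
            "endpoint_b": {"$ref": "#/$defs/point"},
            "known_length_cm": {"type": "number", "exclusiveMinimum": 0}
          }
        },
        "landmarks": {
          "type": "object",
          "required": ["SN", "UMB"],
          "propertyNames": {
            "enum": ["SN", "UMB", "N_R", "N_L", "IMFA_R", "IMFA_L",
                     "UPA_R", "UPA_L", "LB_R", "LB_L", "MB_R", "MB_L"]
          },
          "additionalProperties": {"$ref": "#/$defs/point"}
        }
      }
    }
  }
}
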
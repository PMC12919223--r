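{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Patient record (one JSON object per line in a .jsonl file)",
  "type": "object",
  "required": ["patient_id", "sex", "birth_week", "record_end_week", "events"],
  "properties": {
    "patient_id": { "type": "string", "minLength": 1 },
    "sex": { "enum": ["male", "female"] },
    "birth_week": {
      "type": "integer",
      "maximum": 0,
      "description": "weeks relative to the first recorded DX code (week 0)"
    },
    "record_end_week": { "type": "integer", "minimum": 0 },
    "events": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["channel", "code", "week"],
        "properties": {
          "channel": { "enum": ["DX", "RX", "PROC"] },
          "code": { "type": "string", "minLength": 1 },
          "week": { "type": "integer", "minimum": 0 }
        }
      },
      "description": "sorted by week, ascending"
    }
  }
}
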
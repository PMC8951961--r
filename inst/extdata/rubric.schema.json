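{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "nbspanel rubric configuration",
  "description": "Three-pillar weighted ordinal scoring rubric for prioritizing disorders for newborn screening panels. Points are non-negative multiples of 0.5; each criterion's max_points equals the maximum of its level points; each pillar's cap equals the sum of its criteria's max_points; total_max equals the sum of the caps; the recommendation threshold lies in [0, total_max].",
  "type": "object",
  "required": ["name", "version", "threshold", "pillars"],
  "properties": {
    "name": { "type": "string" },
    "version": { "type": "string" },
    "threshold": { "type": "number", "minimum": 0, "multipleOf": 0.5 },
    "total_max": { "type": "number", "minimum": 0, "multipleOf": 0.5 },
    "pillars": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["name", "cap", "criteria"],
        "properties": {
          "name": { "type": "string" },
          "cap": { "type": "number", "minimum": 0, "multipleOf": 0.5 },
          "criteria": {
            "type": "array",
            "minItems": 1,
            "items": {
              "type": "object",
              "required": ["name", "max_points", "levels"],
              "properties": {
                "name": { "type": "string" },
                "max_points": { "type": "number", "minimum": 0, "multipleOf": 0.5 },
                "levels": {
                  "type": "array",
                  "minItems": 1,
                  "items": {
                    "type": "object",
                    "required": ["code", "points"],
                    "properties": {
                      "code": { "type": "string" },
                      "label": { "type": "string" },
                      "points": { "type": "number", "minimum": 0, "multipleOf": 0.5 }
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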
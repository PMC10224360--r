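{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "electrome generator configuration",
  "description": "Synthetic electrome cohort: 1/f^beta background plus band-limited oscillatory components, optionally step-modulated in the after phase.",
  "type": "object",
  "properties": {
    "fs": { "type": "number", "exclusiveMinimum": 0, "default": 62.5,
            "description": "sampling rate, Hz" },
    "duration_s": { "type": "number", "exclusiveMinimum": 0, "default": 7200,
                    "description": "phase length, seconds" },
    "n_replicates": { "type": "integer", "minimum": 1, "default": 23 },
    "background_exponent": { "type": "number", "minimum": 0, "default": 1,
                             "description": "beta of the 1/f^beta background" },
    "background_rms": { "type": "number", "minimum": 0, "default": 20,
                        "description": "background rms amplitude, uV" },
    "components": {
      "type": "array",
      "items": {
        "type": "object",
        "properties": {
          "center_hz": { "type": "number", "minimum": 0 },
          "bandwidth_hz": { "type": "number", "minimum": 0, "default": 0,
                            "description": "0 gives a pure sinusoid" },
          "rms_uv": { "type": "number", "minimum": 0 }
        },
        "required": ["center_hz", "rms_uv"]
      }
    },
    "modulation": {
      "type": ["object", "null"],
      "properties": {
        "onset_s": { "type": "number", "minimum": 0, "default": 1200 },
        "band_gains": {
          "type": "object",
          "additionalProperties": { "type": "number", "minimum": 0 },
          "description": "band name -> multiplicative power gain"
        },
        "bands": {
          "type": "array",
          "items": {
            "type": "object",
            "properties": {
              "name": { "type": "string" },
              "f_lo_hz": { "type": "number", "minimum": 0 },
              "f_hi_hz": { "type": "number", "exclusiveMinimum": 0 }
            },
            "required": ["name", "f_lo_hz", "f_hi_hz"]
          }
        }
      },
      "required": ["band_gains"]
    },
    "base_seed": { "type": "integer", "default": 1 }
  },
  "required": ["fs", "duration_s", "n_replicates"]
}
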
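{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "aortaflow pipeline configuration",
  "type": "object",
  "additionalProperties": false,
  "properties": {
    "n_cases": {"type": "integer", "minimum": 0},
    "seed": {"type": "integer"},
    "grid_spacing": {"type": "number", "exclusiveMinimum": 0,
                     "description": "voxel size of the fine field, m"},
    "geometry": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "ascending_length": {"type": "number", "exclusiveMinimum": 0},
        "arch_radius": {"type": "number", "exclusiveMinimum": 0},
        "arch_angle_deg": {"type": "number", "minimum": 0},
        "descending_length": {"type": "number", "minimum": 0},
        "radius_start": {"type": "number", "exclusiveMinimum": 0},
        "radius_end": {"type": "number", "exclusiveMinimum": 0},
        "s_valve": {"type": "number", "minimum": 0},
        "s_stj": {"type": "number", "exclusiveMinimum": 0},
        "s_bca": {"type": ["number", "null"]},
        "d_bca": {"type": "number", "exclusiveMinimum": 0},
        "d_lcc": {"type": "number", "exclusiveMinimum": 0},
        "d_lsa": {"type": "number", "exclusiveMinimum": 0},
        "ds": {"type": "number", "exclusiveMinimum": 0}
      }
    },
    "jet": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "v_peak": {"type": "number", "exclusiveMinimum": 0},
        "jet_radius_fraction": {"type": "number", "exclusiveMinimum": 0,
                                "maximum": 1},
        "offset_fraction": {"type": "number", "minimum": 0,
                            "exclusiveMaximum": 1},
        "offset_angle_deg": {"type": "number"},
        "swirl_ratio": {"type": "number", "minimum": 0},
        "profile_exponent": {"type": "number", "minimum": 1},
        "decay_length": {"type": "number", "exclusiveMinimum": 0}
      }
    },
    "jet_variation": {
      "type": "object",
      "additionalProperties": false,
      "description": "per-case uniform sampling ranges [lo, hi]",
      "patternProperties": {
        "^(v_peak|offset_fraction|offset_angle_deg|swirl_ratio|profile_exponent|jet_radius_fraction)$": {
          "type": "array", "items": {"type": "number"},
          "minItems": 2, "maxItems": 2
        }
      }
    },
    "noise": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "target_spacing": {"type": "array", "items": {"type": "number"},
                           "minItems": 3, "maxItems": 3},
        "noise_sd": {"type": "number", "minimum": 0}
      }
    },
    "analysis": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "section_resolution": {"type": "number", "exclusiveMinimum": 0},
        "eoa_constant": {"type": "number", "exclusiveMinimum": 0},
        "nfd_weighting": {"enum": ["forward", "signed"]},
        "v_max_region": {"type": ["array", "null"],
                         "items": {"type": "number"},
                         "minItems": 2, "maxItems": 2}
      }
    },
    "rheology": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "mu0": {"type": "number", "exclusiveMinimum": 0},
        "mu_inf": {"type": "number", "exclusiveMinimum": 0},
        "n": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1},
        "a": {"type": "number", "exclusiveMinimum": 0},
        "lam": {"type": "number", "exclusiveMinimum": 0},
        "rho": {"type": "number", "exclusiveMinimum": 0}
      }
    },
    "patients_csv": {"type": "string"}
  }
}
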
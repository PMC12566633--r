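{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "recsel run configuration",
  "type": "object",
  "additionalProperties": false,
  "required": ["seed"],
  "properties": {
    "mode": {"enum": ["simulate", "files"], "default": "simulate"},
    "paths": {
      "type": "object",
      "properties": {
        "s0": {"type": "string"},
        "s1": {"type": "string"},
        "id_source": {"type": "string", "default": "GY"}
      }
    },
    "design": {
      "type": "object",
      "required": ["n_progenies"],
      "properties": {
        "n_progenies": {"type": "integer", "minimum": 1},
        "n_checks": {"type": "integer", "minimum": 0, "default": 2},
        "n_reps": {"type": "integer", "minimum": 1, "default": 3},
        "blocks_per_rep": {"type": "integer", "minimum": 1, "default": 14},
        "n_ancestry_groups": {"type": "integer", "minimum": 1, "default": 5}
      }
    },
    "traits": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "base_mean", "sigma2_family", "sigma2_plot"],
        "properties": {
          "name": {"type": "string"},
          "base_mean": {"type": "number"},
          "sigma2_family": {"type": "number", "minimum": 0},
          "sigma2_plot": {"type": "number", "minimum": 0},
          "sigma2_rep": {"type": "number", "minimum": 0, "default": 0},
          "sigma2_block": {"type": "number", "minimum": 0, "default": 0},
          "direction": {"enum": ["maximize", "minimize"], "default": "maximize"}
        }
      }
    },
    "genetic_corr": {
      "type": "array",
      "items": {"type": "array", "items": {"type": "number"}},
      "description": "symmetric unit-diagonal PSD matrix, trait order as in `traits`"
    },
    "depression": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["trait", "mean_id", "sd_id"],
        "properties": {
          "trait": {"type": "string"},
          "mean_id": {"type": "number", "minimum": 0, "exclusiveMaximum": 100},
          "sd_id": {"type": "number", "minimum": 0}
        }
      }
    },
    "weights": {"type": "object", "additionalProperties": {"type": "number"}},
    "directions": {"type": "object", "additionalProperties": {"enum": ["maximize", "minimize"]}},
    "selection_fraction": {"type": "number", "exclusiveMinimum": 0, "maximum": 1, "default": 0.2},
    "strategies": {
      "type": "array",
      "items": {"enum": ["BIA", "SHI", "MMI", "BLUP_GY", "BLUP_ID"]}
    },
    "k_grid": {"type": "array", "items": {"type": "integer", "minimum": 1}},
    "gain_mode": {"enum": ["heritability_adjusted", "differential"], "default": "heritability_adjusted"},
    "out_dir": {"type": "string"},
    "seed": {"type": "integer"},
    "log_level": {"enum": ["quiet", "info"], "default": "info"}
  }
}
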
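{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "wormdev run report",
  "type": "object",
  "required": ["provenance"],
  "properties": {
    "temporal": {
      "type": "object",
      "required": ["birth_time_histogram", "phase_fractions", "hub_reports",
                   "comparisons"],
      "properties": {
        "comparisons": {
          "type": "object",
          "additionalProperties": {"$ref": "#/definitions/comparison"}
        }
      }
    },
    "spatial": {
      "type": "object",
      "required": ["length_class_counts", "appearance_curves",
                   "synapse_breakdown", "comparisons"],
      "properties": {
        "comparisons": {
          "type": "object",
          "additionalProperties": {"$ref": "#/definitions/comparison"}
        }
      }
    },
    "circuits": {
      "type": "object",
      "required": ["circuit_curves"]
    },
    "topology": {
      "type": "object",
      "required": ["small_world"]
    },
    "provenance": {
      "type": "object",
      "required": ["seed", "n_trials", "input", "stage_times", "hatch_time",
                   "package_version"]
    }
  },
  "definitions": {
    "comparison": {
      "type": "object",
      "required": ["observed", "ensemble_mean", "ensemble_sd", "t", "p",
                   "n_trials", "available"],
      "properties": {
        "observed": {"type": ["number", "null"]},
        "ensemble_mean": {"type": ["number", "null"]},
        "ensemble_sd": {"type": ["number", "null"]},
        "t": {"type": ["number", "null"]},
        "p": {"type": ["number", "null"]},
        "n_trials": {"type": "integer"},
        "available": {"type": "boolean"}
      }
    }
  }
}
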
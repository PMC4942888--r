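{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "gridconflict analysis results document",
  "type": "object",
  "required": ["tool", "version", "parameters", "grid", "classifications",
               "dilemmas", "dilemmatic_constructs", "indices"],
  "properties": {
    "tool": {"type": "string"},
    "version": {"type": "string"},
    "parameters": {
      "type": "object",
      "required": ["correlation_threshold", "congruent_gap_max",
                   "discrepant_gap_min", "include_self_ideal",
                   "pole_membership_margin"],
      "properties": {
        "correlation_threshold": {"type": "number"},
        "congruent_gap_max": {"type": "integer"},
        "discrepant_gap_min": {"type": "integer"},
        "include_self_ideal": {"type": "boolean"},
        "pole_membership_margin": {"type": "integer"}
      }
    },
    "grid": {
      "type": "object",
      "required": ["n_constructs", "n_elements", "scale", "elements",
                   "constructs"],
      "properties": {
        "n_constructs": {"type": "integer"},
        "n_elements": {"type": "integer"},
        "scale": {
          "type": "object",
          "required": ["min_rating", "max_rating", "midpoint"],
          "properties": {
            "min_rating": {"type": "integer"},
            "max_rating": {"type": "integer"},
            "midpoint": {"type": "integer"}
          }
        },
        "elements": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["label", "role"],
            "properties": {
              "label": {"type": "string"},
              "role": {"type": "string", "enum": ["self", "ideal", "other"]}
            }
          }
        },
        "constructs": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["left_pole", "right_pole"],
            "properties": {
              "left_pole": {"type": "string"},
              "right_pole": {"type": "string"}
            }
          }
        }
      }
    },
    "classifications": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["construct_index", "left_pole", "right_pole",
                     "category", "self_rating", "ideal_rating", "gap"],
        "properties": {
          "construct_index": {"type": "integer"},
          "left_pole": {"type": "string"},
          "right_pole": {"type": "string"},
          "category": {"type": "string",
                       "enum": ["congruent", "discrepant", "dilemmatic",
                                "neutral"]},
          "self_rating": {"type": "integer"},
          "ideal_rating": {"type": "integer"},
          "gap": {"type": "integer"}
        }
      }
    },
    "dilemmas": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["congruent_index", "discrepant_index", "oriented_r",
                     "self_pole_congruent", "undesired_pole_congruent",
                     "present_pole_discrepant", "desired_pole_discrepant",
                     "prototypical_figures"],
        "properties": {
          "congruent_index": {"type": "integer"},
          "discrepant_index": {"type": "integer"},
          "oriented_r": {"type": "number"},
          "self_pole_congruent": {"type": "string"},
          "undesired_pole_congruent": {"type": "string"},
          "present_pole_discrepant": {"type": "string"},
          "desired_pole_discrepant": {"type": "string"},
          "prototypical_figures": {
            "type": "object",
            "required": ["current_side", "change_side"],
            "properties": {
              "current_side": {"type": "array", "items": {"type": "string"}},
              "change_side": {"type": "array", "items": {"type": "string"}}
            }
          }
        }
      }
    },
    "dilemmatic_constructs": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["construct_index", "left_pole", "right_pole",
                     "left_prototypes", "right_prototypes",
                     "left_extreme", "right_extreme"],
        "properties": {
          "construct_index": {"type": "integer"},
          "left_pole": {"type": "string"},
          "right_pole": {"type": "string"},
          "left_prototypes": {"type": "array", "items": {"type": "string"}},
          "right_prototypes": {"type": "array", "items": {"type": "string"}},
          "left_extreme": {"type": ["integer", "null"]},
          "right_extreme": {"type": ["integer", "null"]}
        }
      }
    },
    "indices": {
      "type": "object",
      "required": ["self_ideal_discrepancy", "self_isolation",
                   "adequacy_of_others", "polarization"],
      "properties": {
        "self_ideal_discrepancy": {"type": "number"},
        "self_isolation": {"type": ["number", "null"]},
        "adequacy_of_others": {"type": ["number", "null"]},
        "polarization": {"type": "number"}
      }
    }
  }
}
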
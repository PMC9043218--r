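{
  "format": "adrtriage report table",
  "dialect": {
    "encoding": "UTF-8",
    "separator": ",",
    "header": true,
    "quoting": "allowed"
  },
  "columns": [
    {"name": "causality_assessment_1", "type": "boolean", "description": "Plausible time relationship to drug intake"},
    {"name": "causality_assessment_2", "type": "boolean", "description": "Matched with known ADR types"},
    {"name": "causality_assessment_3", "type": "boolean", "description": "Response to withdrawal plausible"},
    {"name": "causality_assessment_4", "type": "boolean", "description": "Rechallenge satisfactory"},
    {"name": "causality_assessment_5", "type": "boolean", "description": "Can be explained by other factors"},
    {"name": "severity_assessment_1", "type": "boolean", "description": "Death"},
    {"name": "severity_assessment_2", "type": "boolean", "description": "Carcinogenic, teratogenic, or birth defect"},
    {"name": "severity_assessment_3", "type": "boolean", "description": "Significant or permanent disability or damage to organ function"},
    {"name": "severity_assessment_4", "type": "boolean", "description": "Life threatening"},
    {"name": "severity_assessment_5", "type": "boolean", "description": "Admission or prolonged hospitalization"},
    {"name": "severity_assessment_6", "type": "boolean", "description": "Other significant medical events"},
    {"name": "new_ade", "type": "boolean", "description": "Previously unknown adverse event"},
    {"name": "serious_ade", "type": "boolean", "description": "Serious adverse event (consistent with OR of severity items)"},
    {"name": "gender", "type": "boolean", "description": "Patient gender indicator"},
    {"name": "suspect", "type": "boolean", "description": "Suspected (1) vs co-occurring (0) drug"},
    {"name": "r_assess", "type": "ordinal", "domain": [-1, 1, 2, 3, 4, 5], "description": "Reporter causality assessment; -1 = not assessed"},
    {"name": "ri_assess", "type": "ordinal", "domain": [-1, 1, 2, 3, 4, 5], "description": "Reporter-institute causality assessment; -1 = not assessed"},
    {"name": "muni_assess", "type": "ordinal", "domain": [-1, 1, 2, 3, 4, 5], "description": "Municipal-level causality assessment; -1 = not assessed"},
    {"name": "prov_assess", "type": "ordinal", "domain": [-1, 1, 2, 3, 4, 5], "description": "Provincial-level causality assessment (training label); -1 = not assessed"}
  ],
  "ordinal_coding": {
    "1": "unassessable/unclassifiable",
    "2": "conditional/unclassified",
    "3": "possible",
    "4": "probable/likely",
    "5": "certain",
    "-1": "not assessed"
  },
  "boolean_input_values": ["0", "1", "true", "false", "TRUE", "FALSE"],
  "extra_columns": "preserved verbatim as text"
}
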
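{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "psocap staffing profile",
  "description": "Complete parameter set for one discipline's capacity model: work calendar, DPC/IPC split, group-work program, carryover policy, intervention mix, plus metadata. YAML config files follow the same structure.",
  "type": "object",
  "required": ["schema_version", "discipline", "setting", "calendar", "split", "groups", "carryover", "mix", "notes"],
  "additionalProperties": false,
  "properties": {
    "schema_version": { "type": "integer", "const": 1 },
    "discipline": { "type": "string" },
    "setting": { "enum": ["tertiary", "regional", "community", "other"] },
    "notes": { "type": "string" },
    "calendar": {
      "type": "object",
      "required": ["weekly_hours", "weeks_per_year", "vacation_days", "statutory_holiday_days", "sick_days", "education_days", "daily_break_hours", "hours_per_workday"],
      "additionalProperties": false,
      "properties": {
        "weekly_hours": { "type": "number", "exclusiveMinimum": 0 },
        "weeks_per_year": { "type": "number", "exclusiveMinimum": 0 },
        "vacation_days": { "type": "number", "minimum": 0 },
        "statutory_holiday_days": { "type": "number", "minimum": 0 },
        "sick_days": { "type": "number", "minimum": 0 },
        "education_days": { "type": "number", "minimum": 0 },
        "daily_break_hours": { "type": "number", "minimum": 0 },
        "hours_per_workday": { "type": "number", "exclusiveMinimum": 0 }
      }
    },
    "split": {
      "type": "object",
      "required": ["dpc_fraction"],
      "additionalProperties": false,
      "properties": {
        "dpc_fraction": { "type": "number", "exclusiveMinimum": 0, "maximum": 1 }
      }
    },
    "groups": {
      "type": "object",
      "required": ["groups_per_year", "sessions_per_group", "participants_per_group", "prep_hours_per_group", "facilitation_hours_per_session"],
      "additionalProperties": false,
      "properties": {
        "groups_per_year": { "type": "number", "minimum": 0 },
        "sessions_per_group": { "type": "number", "minimum": 0 },
        "participants_per_group": { "type": "number", "minimum": 0 },
        "prep_hours_per_group": { "type": "number", "minimum": 0 },
        "facilitation_hours_per_session": { "type": "number", "minimum": 0 }
      }
    },
    "carryover": {
      "type": "object",
      "required": ["mode", "explicit_count", "rate", "base_caseload", "hours_per_patient", "contacts_per_patient"],
      "additionalProperties": false,
      "properties": {
        "mode": { "enum": ["explicit_count", "rate_of_base"] },
        "explicit_count": { "type": "number", "minimum": 0 },
        "rate": { "type": "number", "minimum": 0, "exclusiveMaximum": 1 },
        "base_caseload": { "type": ["number", "null"], "minimum": 0 },
        "hours_per_patient": { "type": "number", "exclusiveMinimum": 0 },
        "contacts_per_patient": { "type": "number", "exclusiveMinimum": 0 }
      }
    },
    "mix": {
      "type": "object",
      "required": ["counseling_hours_fraction", "counseling_hours_per_patient", "counseling_contacts_per_patient", "instrumental_hours_per_patient", "instrumental_contacts_per_patient"],
      "additionalProperties": false,
      "properties": {
        "counseling_hours_fraction": { "type": "number", "minimum": 0, "maximum": 1 },
        "counseling_hours_per_patient": { "type": "number", "exclusiveMinimum": 0 },
        "counseling_contacts_per_patient": { "type": "number", "exclusiveMinimum": 0 },
        "instrumental_hours_per_patient": { "type": "number", "exclusiveMinimum": 0 },
        "instrumental_contacts_per_patient": { "type": "number", "exclusiveMinimum": 0 }
      }
    }
  }
}
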
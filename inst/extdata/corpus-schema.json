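{
  "$comment": "Informal schema of the canonical JSON corpus dialect (format_version 1). Absent optional fields are omitted, never null. Keys of the four collections are sorted in the C locale.",
  "type": "object",
  "properties": {
    "format_version": {"const": 1},
    "clock": {"type": "string", "format": "date"},
    "genes": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "properties": {
          "gene_symbol": {"type": "string"},
          "entrez_id": {"type": "number"},
          "summary": {"type": "string"},
          "summary_sources": {"$ref": "#/$defs/sourceList"},
          "aliases": {"type": "array", "items": {"type": "string"}},
          "linkouts": {"type": "array", "items": {"type": "string"}}
        }
      }
    },
    "variants": {
      "type": "object",
      "$comment": "keyed by 'SYMBOL::Variant Name'",
      "additionalProperties": {
        "type": "object",
        "properties": {
          "gene_symbol": {"type": "string"},
          "variant_name": {"type": "string"},
          "aliases": {"type": "array", "items": {"type": "string"}},
          "summary": {"type": "string"},
          "summary_sources": {"$ref": "#/$defs/sourceList"},
          "variant_types": {"type": "array", "items": {"type": "string", "pattern": "^SO:"}},
          "hgvs_expressions": {"type": "array", "items": {"type": "string"}},
          "clinvar_ids": {"type": "array", "items": {"type": "string"}},
          "primary_coordinates": {"$ref": "#/$defs/coordinates"},
          "secondary_coordinates": {"$ref": "#/$defs/coordinates"},
          "variant_group_ids": {"type": "array", "items": {"type": "string"}},
          "allele_registry_key": {"type": "string"},
          "moderation": {"$ref": "#/$defs/moderation"}
        }
      }
    },
    "evidence_items": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["eid"],
        "properties": {
          "eid": {"type": "string"},
          "gene_symbol": {"type": "string"},
          "variant_name": {"type": "string"},
          "source": {"$ref": "#/$defs/source"},
          "variant_origin": {"enum": ["Somatic", "Rare Germline", "Common Germline", "Unknown", "N/A"]},
          "disease": {"type": "string"},
          "could_not_find_disease": {"type": "boolean"},
          "evidence_statement": {"type": "string"},
          "evidence_type": {"enum": ["Predictive", "Diagnostic", "Prognostic", "Predisposing", "Functional"]},
          "evidence_level": {"enum": ["A", "B", "C", "D", "E"]},
          "evidence_direction": {"enum": ["Supports", "Does not support"]},
          "clinical_significance": {"type": "string"},
          "evidence_rating": {"type": "integer", "minimum": 1, "maximum": 5},
          "drugs": {"type": "array", "items": {"type": "string"}},
          "drug_interaction_type": {"enum": ["Combination", "Sequential", "Substitutes"]},
          "phenotypes": {"type": "array", "items": {"type": "string", "pattern": "^HP:"}},
          "submission_comment": {"type": "string"},
          "moderation": {"$ref": "#/$defs/moderation"}
        }
      }
    },
    "assertions": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["aid"],
        "properties": {
          "aid": {"type": "string"},
          "gene_symbol": {"type": "string"},
          "variant_name": {"type": "string"},
          "variant_origin": {"type": "string"},
          "disease": {"type": "string"},
          "assertion_type": {"enum": ["Predictive", "Diagnostic", "Prognostic", "Predisposing"]},
          "assertion_direction": {"enum": ["Supports", "Does not support"]},
          "clinical_significance": {"type": "string"},
          "drugs": {"type": "array", "items": {"type": "string"}},
          "drug_interaction_type": {"type": "string"},
          "phenotypes": {"type": "array", "items": {"type": "string"}},
          "amp_tier": {"enum": ["I", "II", "III", "IV"]},
          "amp_level": {"enum": ["A", "B", "C", "D"]},
          "acmg_codes": {"type": "array", "items": {"type": "string"}},
          "acmg_classification": {"enum": ["Pathogenic", "Likely Pathogenic", "VUS", "Likely Benign", "Benign"]},
          "nccn_guideline": {"type": "string"},
          "nccn_version": {"type": "string"},
          "fda_regulatory_approval": {"type": "boolean"},
          "fda_companion_test": {"type": "boolean"},
          "summary": {"type": "string"},
          "description": {"type": "string"},
          "supporting_eids": {"type": "array", "items": {"type": "string"}},
          "moderation": {"$ref": "#/$defs/moderation"}
        }
      }
    },
    "actors": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "properties": {
          "actor_id": {"type": "string"},
          "role": {"enum": ["Curator", "Editor", "Admin"]},
          "coi_statement_date": {"type": "string", "format": "date"}
        }
      }
    },
    "event_log": {
      "type": "array",
      "items": {
        "type": "object",
        "properties": {
          "seq": {"type": "integer"},
          "action": {"enum": ["register_actor", "submit", "accept", "reject", "propose_revision", "accept_revision", "flag", "resolve_flag", "auto_demote"]},
          "actor_id": {"type": "string"},
          "entity_ref": {"type": "string"},
          "payload": {"type": "object"}
        }
      }
    },
    "extras": {"type": "object"}
  },
  "$defs": {
    "source": {
      "type": "object",
      "properties": {
        "source_type": {"enum": ["PubMed", "ASCO"]},
        "source_id": {"type": "string"},
        "citation": {"type": "string"},
        "clinical_trial_ids": {"type": "array", "items": {"type": "string"}}
      }
    },
    "sourceList": {"type": "array", "items": {"$ref": "#/$defs/source"}},
    "coordinates": {
      "type": "object",
      "properties": {
        "chromosome": {"type": "string"},
        "start": {"type": "number"},
        "stop": {"type": "number"},
        "reference_base": {"type": "string"},
        "variant_base": {"type": "string"},
        "reference_build": {"type": "string"},
        "representative_transcript": {"type": "string"}
      }
    },
    "moderation": {
      "type": "object",
      "properties": {
        "state": {"enum": ["submitted", "accepted", "rejected"]},
        "flagged": {"type": "boolean"},
        "submitter_id": {"type": "string"},
        "decided_by": {"type": "string"},
        "comments": {"type": "array"},
        "revisions": {"type": "array"}
      }
    }
  }
}
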
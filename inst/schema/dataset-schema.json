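{
  "$comment": "Descriptive schema for the mrdsim dataset JSON format, version 1.0. The package validates these rules in code (validate_dataset/read_dataset_json); this document records the contract for interoperability. Field names follow the style of joint MRD-visualization tools; adapters for other tools should map keys from this table.",
  "schema_version": "1.0",
  "top_level_keys": ["metadata", "subjects", "observations", "covariates", "endpoints", "ground_truth"],
  "metadata": {
    "schema_version": "string, '1.0'",
    "time_unit": "string; all times in the file share this unit, t = 0 is treatment start",
    "seed": "integer master seed the dataset was generated from",
    "generator": "string, generating tool and version",
    "colormaps": "optional object: covariate name -> array of '#RRGGBB' 6-digit hex codes",
    "config": "the fully resolved simulation configuration (defaults applied); together with `seed`, sufficient to regenerate the dataset byte-for-byte"
  },
  "subjects": {
    "description": "array of subject objects",
    "fields": {
      "id": "unique string label",
      "subgroup": "response-category label (e.g. CR/PR/SD/PD)",
      "covariates": "object of baseline covariate values (binary 0/1, categorical string, continuous number)",
      "tracks": "optional array of time-variant covariate tracks: {name, windows: [{start, value}]} piecewise-constant",
      "event_time": "end of follow-up (event, dropout, or administrative censoring), > 0 and <= t_max",
      "status": "1 = event, 0 = censored",
      "censor_reason": "'none' (event), 'administrative', or 'dropout'"
    }
  },
  "observations": {
    "description": "long-format array of MRD measurements; no observation occurs after the subject's event_time",
    "fields": {
      "subject_id": "references subjects.id (referential integrity enforced)",
      "time": "assessment time, >= 0",
      "value": "reported MRD value (additive noise is floored at 0); null when missing",
      "raw_value": "pre-floor noisy draw; null when missing",
      "missing": "true for scheduled visits that were missed (retained so missingness is analyzable)",
      "below_lod": "strict value < LoD negativity flag; null for missing visits"
    }
  },
  "covariates": "array of covariate generator specs (name, kind, distribution parameters, optional time_variant.window_starts)",
  "endpoints": "object: endpoint name -> array of {subject_id, time, status}; every subject appears in every endpoint",
  "ground_truth": {
    "description": "omitted in blinded exports",
    "subjects": "array of true trajectory parameters per subject: beta0, beta1, beta2, te, tr (null = never relapses), sigma",
    "hazard": "the hazard specification used (baseline family and parameters, gamma, alpha1-alpha3, link_scale, t_max, dropout_rate)",
    "subgroups": "the subgroup population specs used"
  },
  "conventions": {
    "infinity": "JSON has no Infinity literal; an infinite relapse time is serialized as null",
    "numbers": "full precision (shortest round-trip representation); write->read is the identity",
    "forward_compatibility": "readers warn on unknown keys and schema-version drift, then parse best-effort"
  }
}
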
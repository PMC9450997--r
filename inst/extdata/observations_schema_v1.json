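{
  "schema": "nrimpact observations",
  "version": "v1",
  "format": "CSV, RFC-4180, UTF-8, header row",
  "units": {
    "loss means": "kg N ha-1 season-1",
    "yields": "Mg ha-1",
    "n_rate": "kg N ha-1",
    "temperature": "degC seasonal mean",
    "water_load": "mm season-1 (precipitation + irrigation)",
    "som": "g kg-1",
    "stn": "g kg-1",
    "clay": "g kg-1"
  },
  "columns": [
    {"name": "study_id", "type": "character", "required": true},
    {"name": "site_id", "type": "character", "required": true},
    {"name": "province", "type": "character", "required": false,
     "note": "records without a province pool but are excluded from upscaling"},
    {"name": "crop", "type": "enum", "required": true,
     "levels": ["wheat", "maize", "rice"]},
    {"name": "pathway", "type": "enum", "required": true,
     "levels": ["NH3", "N2O", "NO3"]},
    {"name": "n_source", "type": "enum", "required": true,
     "levels": ["urea", "OCF", "IU", "OA"]},
    {"name": "n_rate", "type": "numeric", "required": true, "min": 0},
    {"name": "placement", "type": "enum", "required": true,
     "levels": ["surface", "subsurface"]},
    {"name": "amendment", "type": "enum", "required": true,
     "levels": ["none", "mulch", "biochar", "inhibitor"]},
    {"name": "loss_treat_mean", "type": "numeric", "required": true, "min": 0},
    {"name": "loss_ctrl_mean", "type": "numeric", "required": true, "min": 0},
    {"name": "yield_treat_mean", "type": "numeric", "required": true, "min_exclusive": 0},
    {"name": "yield_ctrl_mean", "type": "numeric", "required": true, "min_exclusive": 0},
    {"name": "n_treat", "type": "integer", "required": true, "min": 1},
    {"name": "n_ctrl", "type": "integer", "required": true, "min": 1},
    {"name": "disp_treat_kind", "type": "enum", "required": true,
     "levels": ["SD", "SE", "CV", "CI", "t_value", "p_value", "missing"]},
    {"name": "disp_treat_value", "type": "numeric", "required": false,
     "note": "SD/SE in outcome units, CV in percent, t unitless, p in (0,1]"},
    {"name": "disp_treat_lower", "type": "numeric", "required": false,
     "note": "CI lower bound, outcome units"},
    {"name": "disp_treat_upper", "type": "numeric", "required": false},
    {"name": "disp_treat_level", "type": "numeric", "required": false,
     "note": "CI confidence level in (0,1), e.g. 0.95"},
    {"name": "disp_ctrl_kind", "type": "enum", "required": true,
     "levels": ["SD", "SE", "CV", "CI", "t_value", "p_value", "missing"]},
    {"name": "disp_ctrl_value", "type": "numeric", "required": false},
    {"name": "disp_ctrl_lower", "type": "numeric", "required": false},
    {"name": "disp_ctrl_upper", "type": "numeric", "required": false},
    {"name": "disp_ctrl_level", "type": "numeric", "required": false},
    {"name": "temperature", "type": "numeric", "required": false},
    {"name": "water_load", "type": "numeric", "required": false, "min": 0},
    {"name": "soil_ph", "type": "numeric", "required": false,
     "min_exclusive": 0, "max_exclusive": 14},
    {"name": "som", "type": "numeric", "required": false, "min": 0},
    {"name": "stn", "type": "numeric", "required": false, "min": 0},
    {"name": "clay", "type": "numeric", "required": false, "min": 0}
  ],
  "conventional_rate_ranges_kgN_ha": {
    "note": "crop-specific conventional ranges retained as metadata; grouping uses the generic 150/250 cutoffs",
    "wheat": [150, 250],
    "maize": [200, 260],
    "rice": [170, 260]
  }
}
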
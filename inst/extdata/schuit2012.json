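{
  "metadata": {
    "title": "Antepartum multinomial prediction model for the risk of operative delivery (Schuit et al. 2012), coefficients as published",
    "coefficients_source": "published multivariable coefficient table (model 1)",
    "synthetic_ranges": true,
    "ranges_note": "Covariate ranges are plausible clinical ranges chosen for this package; the development-data ranges were not published.",
    "published_case": {
      "description": "Hypothetical case: nulliparous diabetic woman, 32 years, 40 weeks' gestation, expecting a boy, estimated birth weight 3540 g",
      "profile": {
        "age": 32,
        "gestational_age": 40,
        "nulliparous": 1,
        "prev_cs": 0,
        "female": 0,
        "birthweight_100g": 35.4,
        "diabetes": 1
      },
      "probabilities": {
        "IVD-FD": 0.096,
        "CS-FD": 0.051,
        "IVD-FTP": 0.069,
        "CS-FTP": 0.268,
        "spontaneous": 0.516
      },
      "total_points": {
        "IVD-FD": 159,
        "CS-FD": 140,
        "IVD-FTP": 149,
        "CS-FTP": 189
      },
      "note": "Published probabilities and total points derive from the unrounded development model and its unpublished covariate ranges; they are not exactly reproducible from the rounded published coefficients."
    }
  },
  "categories": [
    {"label": "IVD-FD"},
    {"label": "CS-FD"},
    {"label": "IVD-FTP"},
    {"label": "CS-FTP"},
    {"label": "spontaneous", "reference": true}
  ],
  "covariates": [
    {"name": "age", "kind": "continuous", "unit": "years", "range": [16, 45]},
    {"name": "gestational_age", "kind": "continuous", "unit": "weeks", "range": [36, 43]},
    {"name": "nulliparous", "kind": "binary", "unit": "0/1", "range": [0, 1]},
    {"name": "prev_cs", "kind": "binary", "unit": "0/1", "range": [0, 1]},
    {"name": "female", "kind": "binary", "unit": "0/1", "range": [0, 1]},
    {"name": "birthweight_100g", "kind": "continuous", "unit": "100 g", "range": [20, 50]},
    {"name": "diabetes", "kind": "binary", "unit": "0/1", "range": [0, 1]}
  ],
  "intercepts": [-13.1, -15.6, -11.1, -15.4],
  "coefficients": [
    [0.029, 0.26, 2.05, 1.77, -0.19, -0.059, 0.32],
    [0.052, 0.32, 1.13, 1.06, -0.5, -0.079, 0.99],
    [0.054, 0.038, 3.39, 2.39, -0.25, 0.083, -0.24],
    [0.056, 0.13, 2.65, 2.23, -0.013, 0.12, 0.87]
  ]
}
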
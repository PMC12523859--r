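{
  "_comment": "Synthetic representative coefficients for the six published MTFa-to-visual-acuity prediction models. The functional form, light type, prediction scope and ceiling behaviour of each model follow its published description; the numeric coefficients are NOT the original published values (which are not redistributable here) but a fixed representative set anchored to the published qualitative VA-vs-MTFa relationship: VA close to 0.0 logMAR for MTFa above ~25-30, about 0.2 logMAR near MTFa ~7, and steeply worsening below MTFa ~5.",
  "models": {
    "vega2018": {
      "label": "Vega 2018",
      "form": "exponential_decay",
      "light_type": "monochromatic",
      "prediction_scope": "monocular",
      "coefficients": { "a": 0.9, "b": 5.0, "c": 0.0 },
      "va_floor": 0.0
    },
    "fernandez2019a": {
      "label": "Fernandez 2019a",
      "form": "linear",
      "light_type": "monochromatic",
      "prediction_scope": "monocular",
      "coefficients": { "intercept": 0.18, "slope": -0.006 },
      "va_floor": null
    },
    "fernandez2019b": {
      "label": "Fernandez 2019b",
      "form": "exponential_decay",
      "light_type": "monochromatic",
      "prediction_scope": "monocular",
      "coefficients": { "a": 0.25, "b": 14.0, "c": -0.02 },
      "va_floor": null
    },
    "alarcon2016": {
      "label": "Alarcon 2016",
      "form": "inverse_power",
      "light_type": "polychromatic",
      "prediction_scope": "binocular",
      "coefficients": { "a": 1.5, "b": -0.04 },
      "va_floor": null
    },
    "armengol2020a": {
      "label": "Armengol 2020a",
      "form": "inverse_proportional",
      "light_type": "polychromatic",
      "prediction_scope": "monocular",
      "coefficients": { "a": 1.7, "b": -0.03 },
      "va_floor": null
    },
    "armengol2020b": {
      "label": "Armengol 2020b",
      "form": "exponential_decay",
      "light_type": "polychromatic",
      "prediction_scope": "monocular",
      "coefficients": { "a": 0.6, "b": 6.5, "c": -0.01 },
      "va_floor": null
    }
  }
}
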
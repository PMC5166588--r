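{
  "title": "lccusum analysis report",
  "required": {
    "benchmark": "object",
    "phase_rates": "object",
    "schemes": "object",
    "proficiency_index": "number",
    "alarm_index": "number",
    "trace": "array",
    "summary": "object",
    "provenance": "object"
  },
  "children": {
    "benchmark": {
      "required": {
        "events": "number", "n": "number", "estimate": "number",
        "upper": "number", "ci_method": "string", "level": "number"
      }
    },
    "scheme": {
      "required": {
        "phase": "string", "p0": "number", "p1": "number",
        "alpha": "number", "beta": "number", "s": "number", "h": "number",
        "plot_sign": "number"
      }
    }
  }
}
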
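# SYNTHETIC placeholder weight table for the six exposure domains.
# These are illustrative log relative-risk weights matching the package's
# synthetic data generator, NOT the published instrument's weights (which
# are not reproduced here). Override with your own table for real analyses.
domains:
  - name: paternal_age
    reference: "0"
    levels:
      "0": 0.0
      "1": 0.35
  - name: pses
    reference: "0"
    levels:
      "0": 0.0
      "1": 0.50
  - name: obstetric
    reference: "0"
    levels:
      "0": 0.0
      "1": 0.45
  - name: urbanicity
    reference: "0"
    levels:
      "0": 0.0
      "1": 0.25
  - name: childhood_adversity
    reference: "0"
    levels:
      "0": 0.0
      "1": 0.80
  - name: recent_life_events
    reference: "0"
    levels:
      "0": 0.0
      "1": 0.40
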
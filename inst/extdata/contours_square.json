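{
  "structures": [
    {
      "label": "square",
      "contours": [
        {
          "z": 1.0,
          "vertices": [[4.5, 4.5], [24.5, 4.5], [24.5, 24.5], [4.5, 24.5]]
        }
      ]
    }
  ]
}
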
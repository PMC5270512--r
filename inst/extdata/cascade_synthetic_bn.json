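{
  "nodes": ["Raf", "Mek", "Erk"],
  "arities": [3, 3, 3],
  "edges": [
    {
      "parent": "Raf",
      "child": "Mek"
    },
    {
      "parent": "Mek",
      "child": "Erk"
    }
  ],
  "cpts": [
    [
      [0.222759066520298, 0.755559705308273, 0.0216812281714296]
    ],
    [
      [0.785563787408257, 0.200807546179242, 0.0136286664125008],
      [0.508760205584562, 0.316775729407949, 0.174464065007489],
      [0.529616660912882, 0.197521235308894, 0.272862103778224]
    ],
    [
      [0.277806243050382, 0.656406698157421, 0.0657870587921974],
      [0.451688680825306, 0.339446313354406, 0.208865005820288],
      [0.321508270826909, 0.0303784764044749, 0.648113252768616]
    ]
  ]
}
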
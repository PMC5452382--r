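{
  "description": "Demo fixtures: six synthetic peak sets with partial mutual overlap on a 300 kb two-chromosome toy genome, generated by demo_fixture().",
  "generator": "demo_fixture",
  "seed": 20170531,
  "genome": {
    "chr1": 200000,
    "chr2": 100000
  },
  "sets": ["H3K27ac", "H3K4me3", "H3K27me3", "H3K4me2", "cellA_SE", "cellB_SE"]
}
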
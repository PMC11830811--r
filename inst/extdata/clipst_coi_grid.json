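{
  "nodes": ["dmPFC", "dlPFC", "omPFC", "vmPFC", "vlPFC", "Hypothalamus", "ACC", "PCC", "Insula", "Amygdala", "Hippocampus", "Thalamus", "NAcc", "Putamen", "Caudate"],
  "n_coi": 39,
  "coi": [
    {
      "index": 1,
      "region_i": "dmPFC",
      "region_j": "dlPFC"
    },
    {
      "index": 2,
      "region_i": "dmPFC",
      "region_j": "omPFC"
    },
    {
      "index": 3,
      "region_i": "dmPFC",
      "region_j": "vmPFC"
    },
    {
      "index": 4,
      "region_i": "dmPFC",
      "region_j": "vlPFC"
    },
    {
      "index": 5,
      "region_i": "dmPFC",
      "region_j": "PCC"
    },
    {
      "index": 6,
      "region_i": "dlPFC",
      "region_j": "omPFC"
    },
    {
      "index": 7,
      "region_i": "dlPFC",
      "region_j": "vmPFC"
    },
    {
      "index": 8,
      "region_i": "dlPFC",
      "region_j": "vlPFC"
    },
    {
      "index": 9,
      "region_i": "dlPFC",
      "region_j": "ACC"
    },
    {
      "index": 10,
      "region_i": "omPFC",
      "region_j": "vmPFC"
    },
    {
      "index": 11,
      "region_i": "omPFC",
      "region_j": "vlPFC"
    },
    {
      "index": 12,
      "region_i": "omPFC",
      "region_j": "Hypothalamus"
    },
    {
      "index": 13,
      "region_i": "omPFC",
      "region_j": "ACC"
    },
    {
      "index": 14,
      "region_i": "omPFC",
      "region_j": "PCC"
    },
    {
      "index": 15,
      "region_i": "omPFC",
      "region_j": "Insula"
    },
    {
      "index": 16,
      "region_i": "omPFC",
      "region_j": "Hippocampus"
    },
    {
      "index": 17,
      "region_i": "omPFC",
      "region_j": "Thalamus"
    },
    {
      "index": 18,
      "region_i": "omPFC",
      "region_j": "NAcc"
    },
    {
      "index": 19,
      "region_i": "vmPFC",
      "region_j": "vlPFC"
    },
    {
      "index": 20,
      "region_i": "vmPFC",
      "region_j": "Hypothalamus"
    },
    {
      "index": 21,
      "region_i": "vmPFC",
      "region_j": "ACC"
    },
    {
      "index": 22,
      "region_i": "vmPFC",
      "region_j": "PCC"
    },
    {
      "index": 23,
      "region_i": "vmPFC",
      "region_j": "Insula"
    },
    {
      "index": 24,
      "region_i": "vmPFC",
      "region_j": "Hippocampus"
    },
    {
      "index": 25,
      "region_i": "vmPFC",
      "region_j": "Thalamus"
    },
    {
      "index": 26,
      "region_i": "vmPFC",
      "region_j": "NAcc"
    },
    {
      "index": 27,
      "region_i": "vlPFC",
      "region_j": "Hypothalamus"
    },
    {
      "index": 28,
      "region_i": "vlPFC",
      "region_j": "ACC"
    },
    {
      "index": 29,
      "region_i": "vlPFC",
      "region_j": "Insula"
    },
    {
      "index": 30,
      "region_i": "vlPFC",
      "region_j": "Hippocampus"
    },
    {
      "index": 31,
      "region_i": "vlPFC",
      "region_j": "Thalamus"
    },
    {
      "index": 32,
      "region_i": "vlPFC",
      "region_j": "NAcc"
    },
    {
      "index": 33,
      "region_i": "Hypothalamus",
      "region_j": "Insula"
    },
    {
      "index": 34,
      "region_i": "Hypothalamus",
      "region_j": "Amygdala"
    },
    {
      "index": 35,
      "region_i": "ACC",
      "region_j": "Insula"
    },
    {
      "index": 36,
      "region_i": "ACC",
      "region_j": "Amygdala"
    },
    {
      "index": 37,
      "region_i": "ACC",
      "region_j": "Hippocampus"
    },
    {
      "index": 38,
      "region_i": "ACC",
      "region_j": "Thalamus"
    },
    {
      "index": 39,
      "region_i": "Amygdala",
      "region_j": "Thalamus"
    }
  ]
}
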
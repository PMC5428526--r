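{
  "protocol": "full_length",
  "provenance": "documented 6-gene x 5-cell QC toy",
  "n_genes": 6,
  "n_cells": 5
}
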
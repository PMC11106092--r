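.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", ".I", ".N", ".SD", "clus", "run", "scan", "rt", "mz", "intensity",
  "apex", "nScans", "scanMin", "scanMax", "charge", "sample_id",
  "feature_id"))
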
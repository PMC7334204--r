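# data.table NSE column names
utils::globalVariables(c(
  ".", ".I", ".N", "participant_id", "taxon_id", "obs_date", "x", "y",
  "cell_id", "count", "n_records", "n_taxa", "n_active_days", "rank",
  "rarity_value", "component", "group", "metric", "loading", "centre",
  "log10_n_records", "k", "ssi", "asw"
))
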
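# Small fixtures shared across test files.

# A constant single-area ledger: `n_months` months, two categories, fixed
# amounts and enrollment.
constant_ledger <- function(n_months = 6, wages = 1000, transport = 100,
                            enrollment = 500, creches = 20) {
  do.call(rbind, lapply(seq_len(n_months), function(m) {
    data.frame(month = m, area = 1,
               category = c("wages_field", "transportation"),
               amount = c(wages, transport),
               enrollment = enrollment, creches = creches,
               stringsAsFactors = FALSE)
  }))
}

table2_totals <- function() {
  p <- default_cost_params()
  setNames(p$annual, p$category)
}
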
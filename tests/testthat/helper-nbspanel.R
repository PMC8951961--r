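# Independent brute-force Kendall tau-b: explicit concordant/discordant
# pair counts with the tie correction. Oracle for rank_concordance().
brute_force_tau_b <- function(x, y) {
  n <- length(x)
  conc <- 0
  disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1
      if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x)
  ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
}

# A minimal single-disorder evidence record, overridable field by field.
make_evidence <- function(...) {
  base <- list(disorder_id = "dx", name = "Example disorder",
               disorder_class = "other", severity_level = "S0",
               onset_class = "symptomatic_at_birth_or_unknown",
               prevalence = NA_real_, prevalence_provenance = "unknown",
               dbs_status = "none",
               performance_class = "insufficient_or_none",
               treatment_availability = "none", outcomes_level = "O0")
  utils::modifyList(base, list(...))
}

as_evidence_tbl <- function(records) {
  do.call(rbind, lapply(records, function(r) tibble::as_tibble(r)))
}
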
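## Statistical simulation helpers shared by module and acceptance tests.
## These simulate at the count level (binomial/multinomial/exponential),
## independently of the spatial generator, so GLM calibration is checked
## against data where the fitted model's sampling assumptions hold.

## per-tumor interface/off-interface cells drawn from multinomial
## compositions
simulate_interface_cohort <- function(n_tumors, probs_iface, probs_off,
                                      n_iface = 150, n_off = 250) {
  rows <- list()
  for (t in seq_len(n_tumors)) {
    k1 <- as.vector(rmultinom(1, n_iface, probs_iface))
    k0 <- as.vector(rmultinom(1, n_off, probs_off))
    ph <- names(probs_iface)
    rows[[t]] <- data.frame(
      image_id = paste0("img", t), patient_id = paste0("P", t),
      phenotype = c(rep(ph, k1), rep(ph, k0)),
      at_interface = rep(c(TRUE, FALSE), c(n_iface, n_off)))
  }
  d <- do.call(rbind, rows)
  d$cell_id <- seq_len(nrow(d))
  d$compartment <- "tme"
  d
}

enrich_on <- function(d) {
  flags <- data.frame(image_id = d$image_id, cell_id = d$cell_id,
                      at_tumor_stroma = d$at_interface,
                      perivascular = FALSE)
  interface_enrichment(d, flags, "tumor_stroma")
}

## structure-fraction table with binomially sampled connection counts;
## p_by_label gives the connection probability for label 0 and 1
simulate_fractions_accept <- function(n, p_by_label, label,
                                      total_mean = 800,
                                      n_structures = 1) {
  totals <- rpois(n, total_mean) + 50
  out <- data.frame(patient_id = paste0("P", seq_len(n)),
                    check.names = FALSE)
  for (s in seq_len(n_structures)) {
    k <- rbinom(n, totals, p_by_label[label + 1])
    out[[paste0("S", s)]] <- k / totals
  }
  out$total_connections <- totals
  out
}

## survival cohort driven by the discretized 0-3 structure score
simulate_survival <- function(n, log_hr_per_score, seed,
                              her2_effect = 0, her2_link = 0,
                              base_rate = 0.01, cens_rate = 0.006) {
  withr::with_seed(seed, {
    ids <- paste0("P", seq_len(n))
    f <- ifelse(runif(n) < 0.25, 0, runif(n, 0.01, 0.6))
    cats <- discretize_connectivity(
      data.frame(patient_id = ids, S1 = f, check.names = FALSE))
    her2 <- rbinom(n, 1, plogis(-1.5 + her2_link * cats$score))
    rate <- base_rate * exp(log_hr_per_score * cats$score +
                            her2_effect * her2)
    t_ev <- rexp(n, rate); t_c <- rexp(n, cens_rate)
    clin <- data.frame(patient_id = ids, er_status = "pos",
                       her2_status = ifelse(her2 == 1, "pos", "neg"),
                       dss_time_months = pmax(pmin(t_ev, t_c), 0.01),
                       dss_event = as.integer(t_ev <= t_c))
    list(cats = cats, clin = clin)
  })
}
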
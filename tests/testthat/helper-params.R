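# Scripted parameter sets for deterministic traces and law checks.

# flat life table: nobody dies of other causes before the terminal age
immortal_life_table <- function() {
  lt <- make_life_table(0, 0, 0)
  lt$qx[110] <- 1
  lt
}

# onset hazard concentrated in one age-year (rate 1000 => onset ~ at `age`)
spike_hazard <- function(age, rate = 1000) {
  h <- rep(0, 110)
  h[age + 1] <- rate
  h
}

# a default set rewritten for scripted traces: forced onset age, fixed growth
# rate, optional spread/surfacing/screening behavior switched off or pinned
trace_params <- function(onset_age = 45,
                         gamma = 0.5,
                         insitu_fraction = 0,
                         insitu_progression_prob = 0.2,
                         nodal_pmax = 0, nodal_k = 0.15,
                         distant_pmax = 0,
                         c0 = 0, dref = 15,
                         smax = 1, d50 = 5, k = 10,
                         sens_insitu = 0,
                         fp_recall_rate = 0,
                         life_table = immortal_life_table(),
                         seed = 1) {
  p <- make_default_params(seed)
  p$life_table <- life_table
  p$onset_hazard <- spike_hazard(onset_age)
  p$insitu_fraction <- insitu_fraction
  p$insitu_progression_prob <- insitu_progression_prob
  p$growth$meanlog <- log(gamma)
  p$growth$sdlog <- 0
  p$stage_model$nodal <- list(pmax = nodal_pmax, d50 = 25, k = nodal_k)
  p$stage_model$distant <- list(pmax = distant_pmax, d50 = 35, k = 0.12)
  p$clinical_detection <- list(c0 = c0, dref = dref)
  p$sensitivity <- list(smax = smax, d50 = d50, k = k, insitu = sens_insitu)
  p$fp_recall_rate <- fp_recall_rate
  validate_params(p)
}

# chi-square goodness of fit of integer waiting times against a geometric law
# with success probability prob (support `from`, `from`+1, ...)
expect_geometric <- function(x, prob, from = 1, alpha = 0.01, max_bin = 20) {
  k <- pmin(round(x - from), max_bin) # collapse the tail into one bin
  obs <- tabulate(k + 1, nbins = max_bin + 1)
  pk <- prob * (1 - prob)^(0:(max_bin - 1))
  pk <- c(pk, 1 - sum(pk))
  keep <- pk * length(x) >= 5
  chi2 <- sum((obs[keep] - length(x) * pk[keep])^2 / (length(x) * pk[keep]))
  crit <- stats::qchisq(1 - alpha, df = sum(keep) - 1)
  expect_lt(chi2, crit)
}
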
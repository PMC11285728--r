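# Fixtures and independent oracles built in code.

# A competition record from explicit proportions and a total event count.
record_from_props <- function(p_t0, p_t1, n = 1000, strain = "S1",
                              arg = "ARG1", env = "DM250", block = "B1",
                              dilution = 100) {
  as_competition_records(data.frame(
    strain_id = strain, arg_id = arg, environment = env, block = block,
    test_day0 = round(n * p_t0), ref_day0 = n - round(n * p_t0),
    test_day1 = round(n * p_t1), ref_day1 = n - round(n * p_t1),
    dilution = dilution, stringsAsFactors = FALSE
  ))
}

# Direct evaluation of the printed fitness formula from proportions —
# independent of the count-based implementation path.
w_oracle <- function(p_t0, p_t1, dilution = 100) {
  log(dilution * p_t1 / p_t0) / log(dilution * (1 - p_t1) / (1 - p_t0))
}

# Numerical-integration oracle for the batch-growth pair competition:
# exponential growth after lag, fine time-stepping, growth stops when the
# shared resource is exhausted.
oracle_pair_fold <- function(lag_a, rate_a, yield_a, lag_b, rate_b, yield_b,
                             resource, cycle_hours = 24, dt = 1e-3) {
  n0 <- 0.5
  na <- n0; nb <- n0
  used <- 0
  t <- 0
  while (t < cycle_hours) {
    t2 <- min(t + dt, cycle_hours)
    na2 <- n0 * exp(rate_a * max(0, t2 - lag_a))
    nb2 <- n0 * exp(rate_b * max(0, t2 - lag_b))
    used2 <- (na2 - n0) / yield_a + (nb2 - n0) / yield_b
    if (used2 >= resource) {
      # linear interpolation inside the step
      frac <- (resource - used) / (used2 - used)
      na <- na + (na2 - na) * frac
      nb <- nb + (nb2 - nb) * frac
      break
    }
    na <- na2; nb <- nb2; used <- used2
    t <- t2
  }
  c(a = na / n0, b = nb / n0)
}

# Construct a wf_sim object with prescribed final frequencies, for testing
# persistence classification in isolation. `final` is types x replicates.
manual_sim <- function(final, strains, args) {
  k <- nrow(final); R <- ncol(final)
  freq <- array(NA_real_, dim = c(k, 2, R),
                dimnames = list(type = paste(strains, args, sep = ":"),
                                generation = NULL, replicate = NULL))
  freq[, 1, ] <- 1 / k
  freq[, 2, ] <- final
  structure(list(
    freq = freq,
    drawn_fitness = matrix(1, k, R),
    types = data.frame(strain_id = strains, arg_id = args,
                       stringsAsFactors = FALSE),
    config = sim_config(replicates = R, min_replicates_persist = 5),
    n_redraws = 0L
  ), class = "wf_sim")
}
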
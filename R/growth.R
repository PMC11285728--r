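# Baseline fitness of progenitor strains from growth-curve parameters.
# Direct head-to-head competition of divergent strains can be distorted by
# interference (colicins, phage), so baseline fitness is reconstructed from
# resource use alone: each strain's realized growth in an in-silico 50:50
# batch competition against a reference strain under one shared limiting
# resource.

# Fold-change of two competitors over one batch cycle. Each grows
# exponentially at its own rate after its lag, and growth stops for both
# when the shared resource is exhausted (or at the end of the cycle).
# Initial density is 0.5 each; yields convert biomass to resource use.
pair_fold_change <- function(lag_a, rate_a, yield_a,
                             lag_b, rate_b, yield_b,
                             resource, cycle_hours) {
  n0 <- 0.5
  consumed <- function(t) {
    n0 * (exp(rate_a * max(0, t - lag_a)) - 1) / yield_a +
      n0 * (exp(rate_b * max(0, t - lag_b)) - 1) / yield_b
  }
  t_star <- if (consumed(cycle_hours) <= resource) {
    cycle_hours
  } else {
    stats::uniroot(function(t) consumed(t) - resource,
                   c(0, cycle_hours), tol = 1e-10)$root
  }
  c(a = exp(rate_a * max(0, t_star - lag_a)),
    b = exp(rate_b * max(0, t_star - lag_b)))
}

#' Baseline strain fitness from growth parameters
#'
#' For each strain, simulates a 50:50 batch competition against the
#' reference strain: both grow exponentially after their lags under a
#' single limiting resource sized so that a reference-vs-reference pairing
#' realizes exactly `dilution`-fold net growth within the cycle. The
#' baseline fitness is the ratio of realized log fold-changes,
#' `ln(fold_strain) / ln(fold_reference)`, so the reference has baseline 1
#' exactly. A strain that cannot double within the cycle triggers a warning
#' but its fitness is still computed as-is.
#'
#' @param growth data frame `strain_id`, `lag` (h), `rate` (per h),
#'   `yield` (density per unit resource); see [read_growth()].
#' @param reference_strain strain id all baselines are relative to.
#' @param cycle_hours duration of one batch cycle.
#' @param dilution target net fold-growth of the reference over one cycle.
#' @return Named numeric vector of baseline fitness values, one per strain.
#' @export
baseline_fitness <- function(growth, reference_strain, cycle_hours = 24,
                             dilution = 100) {
  need <- c("strain_id", "lag", "rate", "yield")
  if (!all(need %in% names(growth))) {
    stop("growth must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  i_ref <- match(reference_strain, growth$strain_id)
  if (is.na(i_ref)) {
    stop("reference strain '", reference_strain, "' not in growth table",
         call. = FALSE)
  }
  ref <- growth[i_ref, ]
  # Resource sized so reference-vs-reference realizes `dilution`-fold
  # growth: total consumption (d - 1) / yield_ref at initial density 1.
  resource <- (dilution - 1) / ref$yield
  out <- vapply(seq_len(nrow(growth)), function(i) {
    g <- growth[i, ]
    fold <- pair_fold_change(g$lag, g$rate, g$yield,
                             ref$lag, ref$rate, ref$yield,
                             resource, cycle_hours)
    if (fold["a"] < 2) {
      warning("strain ", g$strain_id, " does not double within the cycle",
              call. = FALSE)
    }
    log(fold[["a"]]) / log(fold[["b"]])
  }, numeric(1))
  stats::setNames(out, growth$strain_id)
}

#' Combine baseline fitness with ARG effects
#'
#' The fitness of a strain x ARG combination is the strain's baseline
#' fitness multiplied by the ARG's effect ratio in that strain; the
#' measurement sd of the effect is scaled by the baseline. The vector
#' column, whose effect is fixed at 1, therefore equals the baseline
#' exactly. Combinations with no estimate (n = 0 or missing mean) are
#' dropped with a message, never treated as zero.
#'
#' @param baseline named numeric vector from [baseline_fitness()].
#' @param effects an [effect_matrix()].
#' @return Data frame `strain_id`, `arg_id`, `mean`, `sd` ready for
#'   [wright_fisher()].
#' @export
combine_fitness <- function(baseline, effects) {
  stopifnot(inherits(effects, "effect_matrix"))
  strains <- rownames(effects$mean)
  missing_strains <- setdiff(strains, names(baseline))
  if (length(missing_strains) > 0) {
    stop("baseline missing strain(s): ",
         paste(missing_strains, collapse = ", "), call. = FALSE)
  }
  b <- baseline[strains]
  mean_f <- effects$mean * b
  sd_f <- effects$sd * b
  out <- data.frame(
    strain_id = rep(strains, times = ncol(mean_f)),
    arg_id = rep(colnames(mean_f), each = nrow(mean_f)),
    mean = as.vector(mean_f),
    sd = as.vector(sd_f),
    stringsAsFactors = FALSE
  )
  miss <- !is.finite(out$mean)
  if (any(miss)) {
    message("dropping ", sum(miss),
            " strain x ARG combination(s) with no estimate")
    out <- out[!miss, , drop = FALSE]
  }
  no_sd <- !is.finite(out$sd)
  if (any(no_sd)) {
    message(sum(no_sd), " combination(s) lack a replicate sd ",
            "(single replicate); treated as sd 0")
    out$sd[no_sd] <- 0
  }
  rownames(out) <- NULL
  out
}
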
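# Central model-fitting interface: from raw competition records to an
# object holding record-level fitness, the strain x ARG effect table, and
# many-against-one tests of each ARG versus the vector control.

#' Fit ARG fitness effects from competition records
#'
#' Runs the full estimation pipeline: (1) the start-frequency quality
#' filter ([filter_start_frequency()]); (2) record-level relative fitness
#' ([relative_fitness()]); (3) aggregation into per strain x ARG x
#' environment effects with 95% t-intervals ([aggregate_effects()]);
#' (4) many-against-one tests of each ARG against the vector control
#' ([many_to_one_test()]), both per strain (on replicate fitness values
#' within the strain) and overall per environment (on strain-centred
#' fitness values pooled across strains, so between-strain baseline
#' differences do not masquerade as ARG effects).
#'
#' @param records a `competition_records` data frame (see
#'   [read_competitions()]).
#' @param target,tolerance,relative filter settings, see
#'   [filter_start_frequency()].
#' @param conf confidence level for effect intervals.
#' @param n_resamples resamples for the max-|t| adjustment.
#' @param seed seed for the resampling streams.
#' @return An object of class `arg_fit` with elements `fitness`
#'   (record-level table including `W`), `effects` (`arg_effect_table`
#'   with `p_adj` per strain x ARG), `overall` (per-environment ARG-level
#'   tests), `filter` (counts and per-record reasons), and `call`.
#' @seealso [effect_matrix()] to extract the simulator input;
#'   [simulate.arg_fit()] to generate synthetic replicate data from the
#'   fitted effects.
#' @export
#' @examples
#' cfg <- synth_config(n_strains = 3, n_args = 2, replicates = 6, seed = 2)
#' recs <- gen_competitions(gen_effect_matrix(cfg)$truth, cfg)
#' fit <- fit_arg_effects(recs, n_resamples = 199)
#' coef(fit)
fit_arg_effects <- function(records, target = 0.5, tolerance = 0.15,
                            relative = FALSE, conf = 0.95,
                            n_resamples = 999, seed = 1) {
  records <- as_competition_records(as.data.frame(records))
  flt <- filter_start_frequency(records, target = target,
                                tolerance = tolerance, relative = relative)
  fitness <- relative_fitness(flt$retained)
  effects <- aggregate_effects(fitness, conf = conf)

  usable <- fitness[fitness$W_ok, , drop = FALSE]
  # Per-strain many-against-one: ARG replicates vs the strain's own vector
  # replicates, within each environment.
  effects$p_adj <- NA_real_
  for (env in unique(usable$environment)) {
    fe <- usable[usable$environment == env, , drop = FALSE]
    for (st in unique(fe$strain_id)) {
      fs <- fe[fe$strain_id == st, , drop = FALSE]
      ok <- VECTOR_LABEL %in% fs$arg_id &&
        all(table(fs$arg_id) >= 2) && length(unique(fs$arg_id)) >= 2
      if (!ok) next
      tst <- many_to_one_test(fs$W, fs$arg_id, control = VECTOR_LABEL,
                              n_resamples = n_resamples,
                              seed = derive_seed(seed, paste0(env, st)))
      i <- match(paste(st, tst$group, env),
                 paste(effects$strain_id, effects$arg_id,
                       effects$environment))
      effects$p_adj[i] <- tst$p_adj
    }
  }

  # Overall per-ARG tests: strain-centred fitness pooled across strains.
  overall <- list()
  for (env in unique(usable$environment)) {
    fe <- usable[usable$environment == env, , drop = FALSE]
    vec_means <- tapply(fe$W[fe$arg_id == VECTOR_LABEL],
                        fe$strain_id[fe$arg_id == VECTOR_LABEL], mean)
    has_vec <- fe$strain_id %in% names(vec_means)
    fe <- fe[has_vec, , drop = FALSE]
    centred <- fe$W - unname(vec_means[fe$strain_id])
    if (VECTOR_LABEL %in% fe$arg_id &&
        length(unique(fe$arg_id)) >= 2 &&
        all(table(fe$arg_id) >= 2)) {
      tst <- many_to_one_test(centred, fe$arg_id, control = VECTOR_LABEL,
                              n_resamples = n_resamples,
                              seed = derive_seed(seed, paste0("ov", env)))
      ratio <- tapply(fe$W / unname(vec_means[fe$strain_id]), fe$arg_id,
                      mean)
      tst$environment <- env
      tst$mean_ratio <- unname(ratio[tst$group])
      tst$cost_pct <- (1 - tst$mean_ratio) * 100
      overall[[env]] <- tst
    }
  }
  overall <- if (length(overall) > 0) {
    do.call(rbind, c(overall, make.row.names = FALSE))
  } else {
    NULL
  }

  structure(list(
    fitness = fitness,
    effects = effects,
    overall = overall,
    filter = list(
      n_total = nrow(records),
      n_removed = nrow(flt$removed),
      removed = flt$removed,
      reasons = flt$reasons
    ),
    conf = conf,
    call = match.call()
  ), class = "arg_fit")
}

#' @export
print.arg_fit <- function(x, ...) {
  envs <- unique(x$effects$environment)
  cat("ARG fitness-effect fit\n")
  cat("  records:", x$filter$n_total,
      sprintf("(%d removed by start-frequency filter)\n", x$filter$n_removed))
  cat("  strains:", length(unique(x$effects$strain_id)),
      " ARGs:", length(setdiff(unique(x$effects$arg_id), VECTOR_LABEL)),
      " environments:", paste(envs, collapse = ", "), "\n")
  if (!is.null(x$overall)) {
    cat("overall ARG effects (vs vector control):\n")
    print(x$overall[, c("environment", "group", "mean_ratio", "cost_pct",
                        "p_adj")], digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' Summarize an ARG fitness-effect fit
#'
#' @param object an `arg_fit` object.
#' @param ... unused.
#' @return The object, invisibly, after printing the overall per-ARG table
#'   and a per-strain significance summary.
#' @export
summary.arg_fit <- function(object, ...) {
  print(object)
  sig <- object$effects[!is.na(object$effects$p_adj) &
                          object$effects$p_adj < 0.05 &
                          object$effects$arg_id != VECTOR_LABEL, ,
                        drop = FALSE]
  cat("\nstrain x ARG combinations with adjusted p < 0.05:",
      nrow(sig), "\n")
  if (nrow(sig) > 0) {
    print(sig[, c("strain_id", "arg_id", "environment", "n",
                  "effect_ratio", "ci_low", "ci_high", "p_adj")],
          digits = 4, row.names = FALSE)
  }
  invisible(object)
}

#' Effect-ratio matrix of a fit
#'
#' @param object an `arg_fit` object.
#' @param environment environment to extract (required if several).
#' @param ... unused.
#' @return Numeric matrix strains x ARGs of mean effect ratios.
#' @export
coef.arg_fit <- function(object, environment = NULL, ...) {
  effect_matrix(object$effects, environment = environment)$mean
}

#' Plot ARG effects with confidence intervals
#'
#' Base-graphics dot plot: one column per ARG, one point per strain with
#' its 95% t-interval, and a dashed line at no effect.
#'
#' @param x an `arg_fit` object.
#' @param environment environment to plot (required if several).
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.arg_fit <- function(x, environment = NULL, ...) {
  eff <- x$effects
  envs <- unique(eff$environment)
  if (is.null(environment)) {
    if (length(envs) > 1) stop("pick an environment: ",
                               paste(envs, collapse = ", "), call. = FALSE)
    environment <- envs
  }
  eff <- eff[eff$environment == environment &
               eff$arg_id != VECTOR_LABEL, , drop = FALSE]
  args <- sort(unique(eff$arg_id))
  xi <- match(eff$arg_id, args) +
    stats::runif(nrow(eff), -0.15, 0.15)
  ylim <- range(c(eff$ci_low, eff$ci_high, eff$effect_ratio), na.rm = TRUE)
  graphics::plot(xi, eff$effect_ratio, xaxt = "n", xlab = "ARG",
                 ylab = "fitness effect (ratio to vector)",
                 xlim = c(0.5, length(args) + 0.5), ylim = ylim, pch = 19,
                 ...)
  graphics::axis(1, at = seq_along(args), labels = args)
  graphics::segments(xi, eff$ci_low, xi, eff$ci_high)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Simulate competition records from a fitted effect matrix
#'
#' Draws new synthetic competition datasets whose true effects are the
#' fitted mean effect ratios, using the synthetic-data generator. Useful
#' for parametric-bootstrap checks of the estimation pipeline.
#'
#' @param object an `arg_fit` object.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param environment environment to simulate from (required if several).
#' @param config a [synth_config()] providing noise settings; its
#'   dimensions are overridden by the fitted matrix.
#' @param ... unused.
#' @return A list of `nsim` `competition_records` data frames.
#' @export
simulate.arg_fit <- function(object, nsim = 1, seed = 1,
                             environment = NULL, config = synth_config(),
                             ...) {
  em <- effect_matrix(object$effects, environment = environment)
  keep <- is.finite(em$mean)
  truth <- data.frame(
    strain_id = rep(rownames(em$mean), times = ncol(em$mean))[keep],
    arg_id = rep(colnames(em$mean), each = nrow(em$mean))[keep],
    effect = em$mean[keep],
    stringsAsFactors = FALSE
  )
  lapply(seq_len(nsim), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(seed, paste0("simfit", i))
    gen_competitions(truth, cfg)
  })
}

#' Tidy replicate-level fitness table
#'
#' Exports the record-level fitness estimates (with filter and validity
#' flags) in a long format suitable for external mixed-model tooling, e.g.
#' crossed random-effects models of strain, ARG and block.
#'
#' @param x an `arg_fit` object.
#' @param ... unused.
#' @return Data frame with one row per retained competition record.
#' @export
as.data.frame.arg_fit <- function(x, ...) {
  as.data.frame(unclass(x$fitness), stringsAsFactors = FALSE)
}
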
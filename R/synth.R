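# Synthetic-data generator. Emulates the statistical structure of the
# competition assays: ~50:50 starting mixes with jitter, ~100-fold net growth
# per daily cycle, strain x ARG fitness effects of a few percent with an
# interaction variance comparable to the main-effect variance, beta-binomial
# (clumping) overdispersion of cytometry counts, and a small rate of
# reference cells losing their plasmid and being miscounted as the test
# competitor.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe the assay conditions the estimators are designed for:
#' 11 host strains by 6 ARGs (plus the empty vector), a grand mean ARG
#' effect of 0.98 (2% cost), strain/ARG/interaction effect standard
#' deviations of 1/1/1.5% so that interaction variance is comparable to the
#' main effects, 10,000 cytometry events per sample, clumping overdispersion
#' rho = 0.02, start-frequency jitter with sd 0.08 around the 50:50 target
#' (so a realistic minority of records falls outside the 15-point filter
#' window), and a per-day plasmid-loss misclassification rate of 0.004.
#'
#' @param n_strains,n_args numbers of host strains and ARGs (vector control
#'   is added automatically).
#' @param grand_mean_effect grand mean ARG fitness effect on the ratio scale
#'   (1 = neutral).
#' @param sd_strain,sd_arg,sd_interaction standard deviations of the strain
#'   main effects, ARG main effects, and strain-by-ARG interaction
#'   deviations, on the effect (ratio) scale.
#' @param n_events cytometry events counted per sample.
#' @param overdispersion_rho beta-binomial intraclass correlation in `[0, 1)`
#'   modelling cell clumping; 0 gives pure binomial counts.
#' @param start_freq_sd standard deviation of the day-0 test-competitor
#'   frequency around the 0.5 target.
#' @param loss_rate fraction of day-1 reference events reassigned to the
#'   test competitor (plasmid-loss misclassification).
#' @param replicates competition replicates per strain x ARG combination.
#' @param seed master seed; fixed seed gives bit-identical output.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_strains = 11, n_args = 6,
                         grand_mean_effect = 0.98,
                         sd_strain = 0.01, sd_arg = 0.01,
                         sd_interaction = 0.015,
                         n_events = 10000, overdispersion_rho = 0.02,
                         start_freq_sd = 0.08, loss_rate = 0.004,
                         replicates = 5, seed = 1) {
  if (n_strains < 1 || n_args < 1) {
    stop("n_strains and n_args must be >= 1", call. = FALSE)
  }
  if (any(c(sd_strain, sd_arg, sd_interaction, start_freq_sd) < 0)) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  if (overdispersion_rho < 0 || overdispersion_rho >= 1) {
    stop("overdispersion_rho must be in [0, 1)", call. = FALSE)
  }
  if (loss_rate < 0 || loss_rate >= 1) {
    stop("loss_rate must be in [0, 1)", call. = FALSE)
  }
  if (n_events < 1 || replicates < 1) {
    stop("n_events and replicates must be >= 1", call. = FALSE)
  }
  structure(list(
    n_strains = as.integer(n_strains), n_args = as.integer(n_args),
    grand_mean_effect = grand_mean_effect, sd_strain = sd_strain,
    sd_arg = sd_arg, sd_interaction = sd_interaction,
    n_events = as.integer(n_events),
    overdispersion_rho = overdispersion_rho,
    start_freq_sd = start_freq_sd, loss_rate = loss_rate,
    replicates = as.integer(replicates), seed = as.integer(seed)
  ), class = "synth_config")
}

#' Generate a true strain-by-ARG effect matrix
#'
#' True effects are additive on the ratio scale:
#' `effect(s, a) = grand_mean + strain_dev(s) + arg_dev(a) + interaction(s, a)`,
#' with each deviation drawn from a centred normal with the configured sd.
#' The vector-control column is fixed at exactly 1.
#'
#' @param config a [synth_config()].
#' @return A list with `matrix` (an [effect_matrix()] whose means are the
#'   true effects, sd 0) and `truth` (a long data frame
#'   `strain_id`, `arg_id`, `effect` used to parameterize
#'   [gen_competitions()] and for recovery tests).
#' @export
gen_effect_matrix <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  strains <- sprintf("ST%02d", seq_len(config$n_strains))
  args <- sprintf("ARG%d", seq_len(config$n_args))
  eff <- with_seed(derive_seed(config$seed, "effect_matrix"), {
    strain_dev <- stats::rnorm(config$n_strains, 0, config$sd_strain)
    arg_dev <- stats::rnorm(config$n_args, 0, config$sd_arg)
    inter <- matrix(
      stats::rnorm(config$n_strains * config$n_args, 0, config$sd_interaction),
      config$n_strains, config$n_args
    )
    config$grand_mean_effect + outer(strain_dev, arg_dev, `+`) + inter
  })
  dimnames(eff) <- list(strains, args)
  full <- cbind(eff, matrix(1, config$n_strains, 1,
                            dimnames = list(strains, VECTOR_LABEL)))
  truth <- data.frame(
    strain_id = rep(strains, times = config$n_args + 1L),
    arg_id = rep(c(args, VECTOR_LABEL), each = config$n_strains),
    effect = as.vector(full),
    stringsAsFactors = FALSE
  )
  mat <- effect_matrix_new(
    mean = full,
    sd = matrix(0, nrow(full), ncol(full), dimnames = dimnames(full)),
    n = matrix(1L, nrow(full), ncol(full), dimnames = dimnames(full))
  )
  list(matrix = mat, truth = truth)
}

# Expected day-1 test frequency for a record with true relative fitness W:
# the unique root in (0, 1) of
#   ln(d * p1 / p0) = W * ln(d * (1 - p1) / (1 - p0)),
# i.e. the day-1 mixture for which the W estimator returns exactly W. The
# left side is increasing and the right side decreasing in p1, so the root
# is unique and the truth is exactly recoverable from noise-free counts.
solve_day1_freq <- function(W, p0, dilution = 100) {
  vapply(seq_along(W), function(i) {
    f <- function(p1) {
      log(dilution * p1 / p0[i]) - W[i] * log(dilution * (1 - p1) / (1 - p0[i]))
    }
    stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }, numeric(1))
}

#' Generate synthetic competition records
#'
#' For each strain x ARG combination (including the vector control) and
#' replicate: the day-0 test frequency is drawn around the 0.5 target with
#' `start_freq_sd` jitter; the expected day-1 frequency is the one for which
#' the relative-fitness estimator returns the combination's true effect at
#' the given dilution; event counts on both days are drawn beta-binomially
#' with `n_events` and `overdispersion_rho`; and a `loss_rate` fraction of
#' day-1 reference events is reassigned to the test competitor to emulate
#' plasmid-loss misclassification.
#'
#' @param truth long truth table from [gen_effect_matrix()]; must cover
#'   every strain x ARG combination including the vector control.
#' @param config a [synth_config()].
#' @param environment environment label stamped on the records.
#' @param replicates number of replicates per combination; defaults to
#'   `config$replicates`.
#' @param dilution net fold-growth per competition cycle.
#' @return A `competition_records` data frame with a `true_W` attribute
#'   (per-record true fitness) for recovery tests.
#' @export
gen_competitions <- function(truth, config, environment = "DM250",
                             replicates = config$replicates,
                             dilution = 100) {
  stopifnot(inherits(config, "synth_config"))
  need <- c("strain_id", "arg_id", "effect")
  if (!all(need %in% names(truth))) {
    stop("truth table must have columns strain_id, arg_id, effect",
         call. = FALSE)
  }
  strains <- unique(truth$strain_id)
  has_vec <- tapply(truth$arg_id, truth$strain_id,
                    function(a) VECTOR_LABEL %in% a)
  if (!all(has_vec)) {
    stop("truth table missing combination: ",
         names(has_vec)[!has_vec][1], " x ", VECTOR_LABEL, call. = FALSE)
  }
  idx <- rep(seq_len(nrow(truth)), each = replicates)
  n <- length(idx)
  with_seed(derive_seed(config$seed, paste0("competitions_", environment)), {
    p0_true <- clamp(stats::rnorm(n, 0.5, config$start_freq_sd), 0.02, 0.98)
    W_true <- truth$effect[idx]
    p1_true <- solve_day1_freq(W_true, p0_true, dilution)
    test0 <- rbetabinom(n, config$n_events, p0_true, config$overdispersion_rho)
    test1 <- rbetabinom(n, config$n_events, p1_true, config$overdispersion_rho)
    ref0 <- config$n_events - test0
    ref1 <- config$n_events - test1
    if (config$loss_rate > 0) {
      lost <- stats::rbinom(n, ref1, config$loss_rate)
      test1 <- test1 + lost
      ref1 <- ref1 - lost
    }
    rec <- data.frame(
      strain_id = truth$strain_id[idx],
      arg_id = truth$arg_id[idx],
      environment = environment,
      block = sprintf("B%02d", rep(seq_len(replicates), nrow(truth))),
      test_day0 = test0, ref_day0 = ref0,
      test_day1 = test1, ref_day1 = ref1,
      dilution = dilution,
      stringsAsFactors = FALSE
    )
    rec <- as_competition_records(rec)
    attr(rec, "true_W") <- W_true
    rec
  })
}

#' Generate a random tree and trait values with known phylogenetic signal
#'
#' Simulates a pure-birth tree scaled to unit height and draws tip traits
#' from a multivariate normal whose covariance is the lambda-transformed
#' shared-path matrix: full Brownian covariance at `lambda_true = 1`,
#' independent tips at `lambda_true = 0`.
#'
#' @param n_tips number of tips (>= 4).
#' @param lambda_true signal strength in `[0, 1]`.
#' @param seed integer seed.
#' @param sigma2 Brownian rate (trait variance per unit tree height).
#' @return A list with `tree` (an [ape::phylo]) and `traits` (named numeric
#'   vector over tips).
#' @export
gen_tree_traits <- function(n_tips, lambda_true, seed = 1, sigma2 = 1) {
  if (n_tips < 4) stop("n_tips must be >= 4", call. = FALSE)
  if (lambda_true < 0 || lambda_true > 1) {
    stop("lambda_true must be in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    tree <- ape::rphylo(n_tips, birth = 1, death = 0)
    tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
    V <- ape::vcv(tree)
    Vl <- lambda_transform(V, lambda_true) * sigma2
    z <- stats::rnorm(n_tips)
    traits <- drop(t(chol(Vl)) %*% z)
    names(traits) <- rownames(V)
    list(tree = tree, traits = traits)
  })
}

#' Generate per-strain growth parameters
#'
#' Lag, maximum growth rate and yield are log-normally jittered around
#' reference values (defaults: 1.5 h lag, 0.8 per hour rate, unit yield),
#' so all parameters stay positive; `spread = 0` gives identical strains.
#'
#' @param n_strains number of strains.
#' @param spread log-scale standard deviation of the jitter (>= 0).
#' @param seed integer seed.
#' @param lag,rate,yield reference parameter values.
#' @return Data frame `strain_id`, `lag`, `rate`, `yield`.
#' @export
gen_growth_params <- function(n_strains, spread = 0.05, seed = 1,
                              lag = 1.5, rate = 0.8, yield = 1) {
  if (spread < 0) stop("spread must be >= 0", call. = FALSE)
  with_seed(derive_seed(seed, "growth"), {
    data.frame(
      strain_id = sprintf("ST%02d", seq_len(n_strains)),
      lag = lag * exp(stats::rnorm(n_strains, 0, spread)),
      rate = rate * exp(stats::rnorm(n_strains, 0, spread)),
      yield = yield * exp(stats::rnorm(n_strains, 0, spread)),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate qPCR Ct measurements with known plasmid copy numbers
#'
#' Ct pairs satisfy `ct_plasmid - ct_chromosome = -log2(copy_number) + noise`,
#' so the comparative-Ct method recovers the input copy numbers exactly when
#' `ct_noise_sd = 0`.
#'
#' @param copy_numbers named positive numeric vector of plasmid-per-
#'   chromosome copy numbers (names are strain ids).
#' @param ct_noise_sd standard deviation of cycle noise added to the
#'   plasmid Ct.
#' @param seed integer seed.
#' @param ct_chromosome baseline chromosomal Ct (cycles).
#' @return Data frame `strain_id`, `ct_plasmid`, `ct_chromosome`.
#' @export
gen_qpcr <- function(copy_numbers, ct_noise_sd = 0, seed = 1,
                     ct_chromosome = 20) {
  if (any(copy_numbers <= 0)) {
    stop("copy numbers must be > 0", call. = FALSE)
  }
  if (is.null(names(copy_numbers))) {
    names(copy_numbers) <- sprintf("ST%02d", seq_along(copy_numbers))
  }
  with_seed(derive_seed(seed, "qpcr"), {
    n <- length(copy_numbers)
    data.frame(
      strain_id = names(copy_numbers),
      ct_plasmid = ct_chromosome - log2(copy_numbers) +
        stats::rnorm(n, 0, ct_noise_sd),
      ct_chromosome = ct_chromosome,
      stringsAsFactors = FALSE
    )
  })
}

#' Write a complete synthetic dataset to a directory
#'
#' Emits the CSV/Newick files the readers consume (`competitions.csv`,
#' `growth.csv`, `qpcr.csv`, `tree.nwk`) plus the generating truth tables
#' (`truth_effects.csv`, `truth_traits.csv`) for recovery checks.
#'
#' @param dir output directory (created if needed).
#' @param config a [synth_config()].
#' @param environment environment label for the competition records.
#' @return Named character vector of written file paths, invisibly.
#' @export
gen_dataset <- function(dir, config = synth_config(),
                        environment = "DM250") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  em <- gen_effect_matrix(config)
  records <- gen_competitions(em$truth, config, environment = environment)
  growth <- gen_growth_params(config$n_strains,
                              seed = derive_seed(config$seed, "gp"))
  copies <- with_seed(derive_seed(config$seed, "cn"), {
    stats::setNames(2^stats::runif(config$n_strains, -1, 2),
                    sprintf("ST%02d", seq_len(config$n_strains)))
  })
  qpcr <- gen_qpcr(copies, ct_noise_sd = 0.1,
                   seed = derive_seed(config$seed, "ct"))
  tt <- gen_tree_traits(max(config$n_strains, 4), lambda_true = 0.5,
                        seed = derive_seed(config$seed, "tree"))
  paths <- c(
    competitions = file.path(dir, "competitions.csv"),
    growth = file.path(dir, "growth.csv"),
    qpcr = file.path(dir, "qpcr.csv"),
    tree = file.path(dir, "tree.nwk"),
    truth_effects = file.path(dir, "truth_effects.csv"),
    truth_traits = file.path(dir, "truth_traits.csv")
  )
  write_competitions(records, paths["competitions"])
  write_growth(growth, paths["growth"])
  write_qpcr(qpcr, paths["qpcr"])
  write_newick(tt$tree, paths["tree"])
  utils::write.csv(em$truth, paths["truth_effects"], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(
    data.frame(tip = names(tt$traits), trait = unname(tt$traits)),
    paths["truth_traits"], row.names = FALSE, quote = FALSE
  )
  invisible(paths)
}
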
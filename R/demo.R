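# One-command synthetic end-to-end demonstration and the run manifest
# shared by all command-line entry points.

#' Write a run manifest
#'
#' Records alongside every output directory what produced it: the
#' subcommand, the configuration, MD5 digests of the named input files, the
#' master seed, package version and a timestamp. Outputs are
#' reconstructible from the manifest plus the inputs it names.
#'
#' @param dir output directory.
#' @param subcommand short label of the stage that ran.
#' @param config list of configuration values (must be JSON-serializable).
#' @param inputs character vector of input file paths to digest.
#' @param seed master seed of the run.
#' @return Path of the manifest file, invisibly.
#' @export
write_manifest <- function(dir, subcommand, config = list(),
                           inputs = character(), seed = NA_integer_) {
  manifest <- list(
    subcommand = subcommand,
    config = config,
    inputs = as.list(stats::setNames(
      unname(tools::md5sum(inputs)), basename(inputs))),
    seed = seed,
    package_version = as.character(utils::packageVersion("argfit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the full synthetic pipeline end to end
#'
#' Generates a synthetic dataset, estimates ARG effects (filter, fitness,
#' aggregation, many-against-one tests), runs the phylogenetic-signal tests
#' on the first ARG's per-strain effects, reconstructs baseline fitness
#' from the growth parameters, simulates the strain x ARG community, and
#' runs a strain/ARG dropout grid. All outputs and a manifest are written
#' to `out_dir`. Sizes default to a small community (5 strains x 3 ARGs)
#' so the whole demonstration runs in well under a minute.
#'
#' @param seed master seed; every stage derives its stream from it.
#' @param out_dir output directory.
#' @param config a [synth_config()] describing the synthetic community.
#' @param sim a [sim_config()] for the community simulation.
#' @return Invisibly, a list with the fitted `arg_fit`, the signal results,
#'   the simulation, the dropout grid, and the output paths.
#' @export
run_demo <- function(seed = 1, out_dir = tempfile("argfit_demo_"),
                     config = synth_config(n_strains = 5, n_args = 3,
                                           replicates = 8, seed = seed),
                     sim = sim_config(pop_size = 2000, generations = 100,
                                      replicates = 10, seed = seed)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- gen_dataset(out_dir, config)

  records <- read_competitions(paths[["competitions"]])
  fit <- fit_arg_effects(records, n_resamples = 499, seed = seed)
  effects_path <- file.path(out_dir, "effects.csv")
  write_effects(fit, effects_path)

  tree <- read_newick(paths[["tree"]])
  em <- effect_matrix(fit$effects)
  first_arg <- setdiff(colnames(em$mean), VECTOR_LABEL)[1]
  traits <- em$mean[, first_arg]
  # strain ids map onto tree tips t1..tn in label order
  names(traits) <- tree$tip.label[seq_along(traits)]
  signal <- list(
    lambda = pagel_lambda(tree, traits),
    K = blomberg_k(tree, traits, n_perm = 199,
                   seed = derive_seed(seed, "demoK"))
  )

  growth <- read_growth(paths[["growth"]])
  base <- baseline_fitness(growth, reference_strain = growth$strain_id[1])
  fitness_table <- combine_fitness(base, em)
  sim_res <- wright_fisher(fitness_table, sim)
  persist <- classify_persistence(sim_res, preset = "strict")
  grid <- dropout_grid(fitness_table, sim, preset = "strict")
  utils::write.csv(dropout_long(grid),
                   file.path(out_dir, "dropout.csv"), row.names = FALSE)
  utils::write.csv(grid$conditions,
                   file.path(out_dir, "dropout_conditions.csv"),
                   row.names = FALSE)

  write_manifest(out_dir, "demo",
                 config = c(unclass(config), unclass(sim)),
                 inputs = unname(paths), seed = seed)
  invisible(list(
    fit = fit, signal = signal, simulation = sim_res,
    persistence = persist, grid = grid, out_dir = out_dir,
    paths = c(paths, effects = effects_path)
  ))
}

#' Write the effects table of a fit to CSV
#'
#' Column layout: `strain_id`, `arg_id`, `environment`, `n`, `mean_ratio`,
#' `mean_diff`, `ci_low`, `ci_high`, `p_adj`.
#'
#' @param fit an `arg_fit` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_effects <- function(fit, path) {
  stopifnot(inherits(fit, "arg_fit"))
  eff <- fit$effects
  out <- data.frame(
    strain_id = eff$strain_id, arg_id = eff$arg_id,
    environment = eff$environment, n = eff$n,
    mean_ratio = eff$effect_ratio, mean_diff = eff$effect_diff,
    ci_low = eff$ci_low, ci_high = eff$ci_high, p_adj = eff$p_adj,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
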
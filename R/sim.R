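# Individual-based Wright-Fisher simulation of strain x ARG communities:
# equal starting numbers of every combination, fitness drawn per replicate
# from the measurement distribution of each combination, multinomial
# resampling each generation, persistence classification, and the
# strain/ARG dropout grid.

#' Configuration for the community simulator
#'
#' @param pop_size population size (individuals).
#' @param generations number of Wright-Fisher generations; one generation
#'   is one whole 24 h batch cycle, over which the fitness estimates are
#'   integrated.
#' @param replicates replicate simulations.
#' @param persistence_threshold final frequency a strain or ARG must exceed
#'   to count as present in a replicate.
#' @param min_replicates_persist number of replicates in which the
#'   threshold must be exceeded for persistence (capped at `replicates`).
#' @param fitness_draw `"per-replicate"` draws each combination's fitness
#'   once per replicate from Normal(mean, sd), reflecting measurement
#'   uncertainty of the estimates; `"fixed-mean"` uses the means;
#'   `"per-generation"` redraws every generation (environmental noise).
#' @param seed master seed.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(pop_size = 10000, generations = 200, replicates = 10,
                       persistence_threshold = 0.02,
                       min_replicates_persist = min(5, replicates),
                       fitness_draw = c("per-replicate", "fixed-mean",
                                        "per-generation"),
                       seed = 1) {
  fitness_draw <- match.arg(fitness_draw)
  if (pop_size < 1) stop("pop_size must be >= 1", call. = FALSE)
  if (generations < 0) stop("generations must be >= 0", call. = FALSE)
  if (persistence_threshold <= 0 || persistence_threshold >= 1) {
    stop("persistence_threshold must be in (0, 1)", call. = FALSE)
  }
  if (min_replicates_persist > replicates) {
    stop("min_replicates_persist must be <= replicates", call. = FALSE)
  }
  structure(list(
    pop_size = as.integer(pop_size),
    generations = as.integer(generations),
    replicates = as.integer(replicates),
    persistence_threshold = persistence_threshold,
    min_replicates_persist = as.integer(min_replicates_persist),
    fitness_draw = fitness_draw,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Draw one fitness value per type, redrawing non-positive values
# (truncation at zero); the number of redraws is recorded.
draw_fitness <- function(mean, sd) {
  w <- stats::rnorm(length(mean), mean, sd)
  redraws <- 0L
  while (any(w <= 0)) {
    bad <- w <= 0
    redraws <- redraws + sum(bad)
    w[bad] <- stats::rnorm(sum(bad), mean[bad], sd[bad])
  }
  list(w = w, redraws = redraws)
}

#' Wright-Fisher simulation of a strain-by-ARG community
#'
#' Initial counts are as equal across types as integer rounding allows
#' (`floor(pop_size / n_types)` each, remainder to the first types in label
#' order). Each generation the next population is a multinomial draw of
#' `pop_size` individuals with probabilities proportional to current
#' frequency times fitness. Fitness values are drawn according to
#' `config$fitness_draw`; non-positive draws are redrawn and counted.
#' Identical config and seed give identical results.
#'
#' @param fitness data frame `strain_id`, `arg_id`, `mean`, `sd` (e.g. from
#'   [combine_fitness()]).
#' @param config a [sim_config()].
#' @return A `wf_sim` object: `freq` (types x generations+1 x replicates
#'   array of frequencies), `drawn_fitness` (types x replicates matrix for
#'   per-replicate draws), `types` (data frame of type labels), `config`,
#'   `n_redraws`.
#' @export
wright_fisher <- function(fitness, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  need <- c("strain_id", "arg_id", "mean", "sd")
  if (!all(need %in% names(fitness))) {
    stop("fitness must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(fitness) < 1) stop("need at least one type", call. = FALSE)
  if (any(!is.finite(fitness$mean)) || any(fitness$mean <= 0)) {
    stop("fitness means must be positive and finite", call. = FALSE)
  }
  k <- nrow(fitness)
  N <- config$pop_size
  G <- config$generations
  R <- config$replicates
  type_labels <- paste(fitness$strain_id, fitness$arg_id, sep = ":")
  counts0 <- rep(N %/% k, k)
  rem <- N - sum(counts0)
  if (rem > 0) counts0[seq_len(rem)] <- counts0[seq_len(rem)] + 1L
  freq <- array(NA_real_, dim = c(k, G + 1L, R),
                dimnames = list(type = type_labels, generation = NULL,
                                replicate = NULL))
  drawn <- matrix(NA_real_, k, R, dimnames = list(type_labels, NULL))
  n_redraws <- 0L
  with_seed(derive_seed(config$seed, "wright_fisher"), {
    for (r in seq_len(R)) {
      w <- switch(config$fitness_draw,
        "fixed-mean" = fitness$mean,
        "per-replicate" = {
          dd <- draw_fitness(fitness$mean, fitness$sd)
          n_redraws <- n_redraws + dd$redraws
          dd$w
        },
        "per-generation" = fitness$mean # redrawn inside the loop
      )
      drawn[, r] <- w
      counts <- counts0
      freq[, 1L, r] <- counts / N
      for (g in seq_len(G)) {
        if (config$fitness_draw == "per-generation") {
          dd <- draw_fitness(fitness$mean, fitness$sd)
          n_redraws <- n_redraws + dd$redraws
          w <- dd$w
        }
        if (max(counts) == N && config$fitness_draw != "per-generation") {
          # monomorphic: dynamics are frozen, fill and stop early
          freq[, (g:G) + 1L, r] <- counts / N
          break
        }
        pr <- counts * w
        counts <- drop(stats::rmultinom(1, N, pr / sum(pr)))
        freq[, g + 1L, r] <- counts / N
      }
    }
  })
  structure(list(
    freq = freq, drawn_fitness = drawn,
    types = fitness[, c("strain_id", "arg_id")],
    config = config, n_redraws = n_redraws
  ), class = "wf_sim")
}

#' @export
print.wf_sim <- function(x, ...) {
  d <- dim(x$freq)
  cat("Wright-Fisher simulation:", d[1], "types,", d[2] - 1,
      "generations,", d[3], "replicates (pop size",
      x$config$pop_size, ")\n")
  fin <- final_frequencies(x)
  top <- sort(rowMeans(fin), decreasing = TRUE)[1:min(3, d[1])]
  cat("top mean final frequencies:\n")
  print(round(top, 4))
  invisible(x)
}

#' Final type frequencies of a simulation
#' @param result a `wf_sim` object.
#' @return Matrix types x replicates of final-generation frequencies.
#' @export
final_frequencies <- function(result) {
  stopifnot(inherits(result, "wf_sim"))
  d <- dim(result$freq)
  matrix(result$freq[, d[2], , drop = FALSE], nrow = d[1],
         dimnames = list(dimnames(result$freq)$type, NULL))
}

#' Plot simulated frequency trajectories
#'
#' One panel of mean frequency trajectories across replicates, one line per
#' strain x ARG combination.
#'
#' @param x a `wf_sim` object.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.wf_sim <- function(x, ...) {
  m <- apply(x$freq, c(1, 2), mean)
  graphics::matplot(t(m), type = "l", lty = 1,
                    xlab = "generation", ylab = "mean frequency", ...)
  invisible(x)
}

#' Classify strain and ARG persistence
#'
#' A strain's (or ARG's) frequency in a replicate is the summed final
#' frequency of all its combinations; it persists when that frequency
#' exceeds the threshold in at least `min_replicates` replicates. By
#' default the criterion comes from the simulation's own [sim_config()];
#' two named presets are provided: `"strict"` (threshold 0.02 in at least
#' 5 replicates) and `"lenient"` (threshold 0.01 in at least 2), with explicit
#' `threshold`/`min_replicates` overriding either.
#'
#' @param result a `wf_sim` object.
#' @param preset optional, `"strict"` or `"lenient"`.
#' @param threshold,min_replicates explicit criterion (overrides preset and
#'   config).
#' @return List with `strains`, `args` (character vectors of persisted
#'   labels) and `table` (per-entity replicate counts above threshold).
#' @export
classify_persistence <- function(result, preset = NULL,
                                 threshold = NULL, min_replicates = NULL) {
  stopifnot(inherits(result, "wf_sim"))
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("strict", "lenient"))
    threshold <- threshold %||% switch(preset, strict = 0.02, lenient = 0.01)
    min_replicates <- min_replicates %||%
      switch(preset, strict = 5L, lenient = 2L)
  }
  threshold <- threshold %||% result$config$persistence_threshold
  min_replicates <- min_replicates %||% result$config$min_replicates_persist
  fin <- final_frequencies(result)
  classify <- function(labels) {
    groups <- unique(labels)
    # replicates x groups matrix of summed final frequencies
    agg <- matrix(vapply(groups, function(g) {
      colSums(fin[labels == g, , drop = FALSE])
    }, numeric(ncol(fin))), nrow = ncol(fin))
    hits <- colSums(agg > threshold)
    data.frame(label = groups, replicates_above = as.integer(hits),
               persisted = hits >= min_replicates,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  st <- classify(result$types$strain_id)
  ar <- classify(result$types$arg_id)
  list(
    strains = st$label[st$persisted],
    args = ar$label[ar$persisted],
    table = rbind(cbind(entity = "strain", st),
                  cbind(entity = "arg", ar)),
    threshold = threshold, min_replicates = min_replicates
  )
}

#' Strain/ARG dropout grid
#'
#' Repeats the community simulation for every condition in
#' (no omission + each strain) x (no omission + each ARG): the named strain
#' and/or ARG is removed from the starting community, the simulation run,
#' and persistence classified. The vector control is never droppable.
#' Per-condition seeds are derived deterministically from the master seed,
#' so conditions are independent of grid order.
#'
#' @param fitness data frame `strain_id`, `arg_id`, `mean`, `sd`.
#' @param config a [sim_config()].
#' @param drop_strains strains to drop one at a time (default all).
#' @param drop_args ARGs to drop one at a time (default all non-vector).
#' @param preset optional persistence preset passed to
#'   [classify_persistence()]; by default the config's criterion is used.
#' @return A `dropout_grid` object: `conditions` (data frame with dropped
#'   labels, persisted strain/ARG sets, and the top combination by mean
#'   final frequency) and `mean_final` (list of per-condition mean final
#'   frequencies by combination).
#' @export
dropout_grid <- function(fitness, config = sim_config(),
                         drop_strains = NULL, drop_args = NULL,
                         preset = NULL) {
  strains <- unique(fitness$strain_id)
  args <- setdiff(unique(fitness$arg_id), VECTOR_LABEL)
  drop_strains <- drop_strains %||% strains
  drop_args <- drop_args %||% args
  if (VECTOR_LABEL %in% drop_args) {
    stop("the vector control cannot be dropped", call. = FALSE)
  }
  bad <- setdiff(drop_strains, strains)
  if (length(bad) > 0) {
    stop("cannot drop unknown strain(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(drop_args, args)
  if (length(bad) > 0) {
    stop("cannot drop unknown ARG(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  grid <- expand.grid(dropped_strain = c(NA_character_, drop_strains),
                      dropped_arg = c(NA_character_, drop_args),
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  mean_final <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ds <- grid$dropped_strain[i]
    da <- grid$dropped_arg[i]
    sub <- fitness
    if (!is.na(ds)) sub <- sub[sub$strain_id != ds, , drop = FALSE]
    if (!is.na(da)) sub <- sub[sub$arg_id != da, , drop = FALSE]
    cfg <- config
    cfg$seed <- derive_seed(config$seed,
                            paste0(ifelse(is.na(ds), "-", ds), "|",
                                   ifelse(is.na(da), "-", da)))
    sim <- wright_fisher(sub, cfg)
    cls <- classify_persistence(sim, preset = preset)
    mf <- rowMeans(final_frequencies(sim))
    mean_final[[i]] <- mf
    top <- names(mf)[which.max(mf)]
    rows[[i]] <- data.frame(
      dropped_strain = ds, dropped_arg = da,
      persisted_strains = paste(cls$strains, collapse = ";"),
      persisted_args = paste(cls$args, collapse = ";"),
      n_persisted_strains = length(cls$strains),
      n_persisted_args = length(cls$args),
      top_combination = top,
      stringsAsFactors = FALSE
    )
  }
  structure(list(
    conditions = do.call(rbind, rows),
    mean_final = mean_final,
    config = config, preset = preset
  ), class = "dropout_grid")
}

#' @export
print.dropout_grid <- function(x, ...) {
  cat("Dropout grid: ", nrow(x$conditions), " conditions (criterion: ",
      x$preset %||% "from config", ")\n", sep = "")
  print(utils::head(x$conditions[, c("dropped_strain", "dropped_arg",
                                     "persisted_strains",
                                     "persisted_args")], 10))
  if (nrow(x$conditions) > 10) cat("...\n")
  invisible(x)
}

#' Long-format table of a dropout grid
#'
#' One row per condition x strain x ARG combination with the mean final
#' frequency and whether the combination's strain and ARG persisted, the
#' layout used to export grid results.
#'
#' @param grid a `dropout_grid` object.
#' @return Data frame in long format.
#' @export
dropout_long <- function(grid) {
  stopifnot(inherits(grid, "dropout_grid"))
  out <- list()
  for (i in seq_len(nrow(grid$conditions))) {
    mf <- grid$mean_final[[i]]
    parts <- strsplit(names(mf), ":", fixed = TRUE)
    cond <- grid$conditions[i, ]
    out[[i]] <- data.frame(
      dropped_strain = cond$dropped_strain,
      dropped_arg = cond$dropped_arg,
      strain_id = vapply(parts, `[`, "", 1),
      arg_id = vapply(parts, `[`, "", 2),
      mean_final_freq = unname(mf),
      strain_persisted = vapply(parts, `[`, "", 1) %in%
        strsplit(cond$persisted_strains, ";")[[1]],
      arg_persisted = vapply(parts, `[`, "", 2) %in%
        strsplit(cond$persisted_args, ";")[[1]],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
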
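# Baseline fitness from growth curves, fitness combination, the
# Wright-Fisher simulator and persistence/dropout logic.

test_that("baseline fitness is 1 for identical strains and the reference", {
  g <- gen_growth_params(4, spread = 0, seed = 2)
  b <- baseline_fitness(g, reference_strain = g$strain_id[1])
  expect_equal(unname(b), rep(1, 4))
})

test_that("baseline fitness responds to rate and lag as growth dictates", {
  g <- data.frame(
    strain_id = c("REF", "FAST", "LAGGY"),
    lag = c(1.5, 1.5, 3.0),
    rate = c(0.8, 0.88, 0.8),
    yield = 1
  )
  b <- baseline_fitness(g, "REF")
  expect_gt(b[["FAST"]], 1)
  expect_lt(b[["LAGGY"]], 1)

  # agreement with an independent time-stepping integration of the same
  # resource-limited pair model
  resource <- 99  # (dilution - 1) / yield_ref
  for (i in 2:3) {
    fold <- oracle_pair_fold(g$lag[i], g$rate[i], g$yield[i],
                             g$lag[1], g$rate[1], g$yield[1], resource)
    expect_equal(b[[g$strain_id[i]]], log(fold[["a"]]) / log(fold[["b"]]),
                 tolerance = 1e-3)
  }

  expect_warning(
    baseline_fitness(data.frame(strain_id = c("REF", "SLOW"),
                                lag = c(1.5, 23.9), rate = c(0.8, 0.1),
                                yield = 1), "REF"),
    "does not double"
  )
  expect_error(baseline_fitness(g, "NOPE"), "reference strain")
})

test_that("combine_fitness multiplies baseline and effect", {
  em <- gen_effect_matrix(
    synth_config(n_strains = 2, n_args = 1, seed = 3))$matrix
  em$mean["ST01", "ARG1"] <- 0.97
  base <- c(ST01 = 1.02, ST02 = 0.99)
  out <- combine_fitness(base, em)
  expect_equal(out$mean[out$strain_id == "ST01" & out$arg_id == "ARG1"],
               1.02 * 0.97)
  # vector column equals baseline exactly
  expect_equal(out$mean[out$arg_id == "VECTOR"], unname(base))
  expect_error(combine_fitness(c(ST01 = 1), em), "missing strain")

  # missing cells are dropped with a message, never zeroed
  em$mean["ST02", "ARG1"] <- NA
  expect_message(out2 <- combine_fitness(base, em), "no estimate")
  expect_false(any(out2$strain_id == "ST02" & out2$arg_id == "ARG1"))
})

test_that("single-type populations stay fixed and sums are conserved", {
  one <- data.frame(strain_id = "S", arg_id = "VECTOR", mean = 1, sd = 0)
  sim <- wright_fisher(one, sim_config(pop_size = 500, generations = 20,
                                       replicates = 3, seed = 1))
  expect_true(all(sim$freq == 1))

  cfg <- synth_config(n_strains = 3, n_args = 2, seed = 5)
  fit <- combine_fitness(
    setNames(rep(1, 3), sprintf("ST%02d", 1:3)),
    gen_effect_matrix(cfg)$matrix
  )
  fit$sd <- 0.01
  sim <- wright_fisher(fit, sim_config(pop_size = 1000, generations = 50,
                                       replicates = 4, seed = 9))
  sums <- apply(sim$freq, c(2, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(sim$freq >= 0))
})

test_that("simulations are reproducible and seeds matter", {
  fit <- data.frame(strain_id = c("A", "B"), arg_id = "VECTOR",
                    mean = c(1, 1.02), sd = c(0.01, 0.01))
  cfg <- sim_config(pop_size = 200, generations = 30, replicates = 5,
                    seed = 42)
  s1 <- wright_fisher(fit, cfg)
  s2 <- wright_fisher(fit, cfg)
  expect_identical(s1$freq, s2$freq)
  expect_identical(s1$drawn_fitness, s2$drawn_fitness)
  cfg2 <- cfg; cfg2$seed <- 43L
  expect_false(identical(wright_fisher(fit, cfg2)$freq, s1$freq))
})

test_that("neutral types keep constant expected frequencies", {
  fit <- data.frame(strain_id = c("A", "B", "C", "D"), arg_id = "VECTOR",
                    mean = 1, sd = 0)
  sim <- wright_fisher(fit, sim_config(pop_size = 5000, generations = 50,
                                       replicates = 40, seed = 7,
                                       fitness_draw = "fixed-mean"))
  fin <- final_frequencies(sim)
  expect_equal(unname(rowMeans(fin)), rep(0.25, 4), tolerance = 0.03)
})

test_that("selection fixes the fittest type faster in larger populations", {
  fit <- data.frame(strain_id = c("A", "B", "C"), arg_id = "VECTOR",
                    mean = c(1, 1.05, 0.97), sd = 0)
  big <- wright_fisher(fit, sim_config(pop_size = 10000, generations = 200,
                                       replicates = 5, seed = 3,
                                       fitness_draw = "fixed-mean"))
  small <- wright_fisher(fit, sim_config(pop_size = 100, generations = 200,
                                         replicates = 50, seed = 3,
                                         fitness_draw = "fixed-mean"))
  f_big <- mean(final_frequencies(big)["B:VECTOR", ])
  f_small <- mean(final_frequencies(small)["B:VECTOR", ])
  expect_gt(f_big, 0.999)
  expect_gte(f_big, f_small)
})

test_that("fitness draws respect the configured mode", {
  fit <- data.frame(strain_id = c("A", "B"), arg_id = "VECTOR",
                    mean = c(1, 1.01), sd = c(0.05, 0.05))
  fixed <- wright_fisher(fit, sim_config(pop_size = 100, generations = 5,
                                         replicates = 3, seed = 2,
                                         fitness_draw = "fixed-mean"))
  expect_equal(unname(fixed$drawn_fitness), matrix(c(1, 1.01), 2, 3))
  drawn <- wright_fisher(fit, sim_config(pop_size = 100, generations = 5,
                                         replicates = 3, seed = 2))
  expect_gt(length(unique(as.vector(drawn$drawn_fitness))), 2)
  # negative draws are redrawn: wide sd still yields positive fitness
  wide <- data.frame(strain_id = "A", arg_id = "VECTOR", mean = 0.1,
                     sd = 2)
  sim <- wright_fisher(wide, sim_config(pop_size = 10, generations = 1,
                                        replicates = 20, seed = 4))
  expect_true(all(sim$drawn_fitness > 0))
  expect_gt(sim$n_redraws, 0)
})

test_that("persistence classification applies both presets correctly", {
  strains <- c("S1", "S1", "S2")
  args <- c("ARG1", "VECTOR", "ARG2")
  # S2:ARG2 at 0.03 in exactly 5 of 10 replicates, 0 otherwise
  fin <- matrix(0, 3, 10)
  fin[3, 1:5] <- 0.03
  fin[1, ] <- 0.5
  fin[2, ] <- 1 - fin[1, ] - fin[3, ]
  sim <- manual_sim(fin, strains, args)

  cls <- classify_persistence(sim, preset = "strict")
  expect_true("S2" %in% cls$strains)
  expect_true("ARG2" %in% cls$args)
  expect_true(all(c("S1") %in% cls$strains))

  # 0.015 in 3/10: fails the strict threshold, passes the lenient one
  fin2 <- fin
  fin2[3, ] <- 0
  fin2[3, 1:3] <- 0.015
  fin2[2, ] <- 1 - fin2[1, ] - fin2[3, ]
  sim2 <- manual_sim(fin2, strains, args)
  expect_false("S2" %in% classify_persistence(sim2, "strict")$strains)
  expect_true("S2" %in% classify_persistence(sim2, "lenient")$strains)

  # extinct everywhere -> never persisted
  fin3 <- fin
  fin3[3, ] <- 0
  fin3[2, ] <- 1 - fin3[1, ]
  sim3 <- manual_sim(fin3, strains, args)
  expect_false("ARG2" %in% classify_persistence(sim3, "lenient")$args)

  # explicit override beats the preset
  cls5 <- classify_persistence(sim2, threshold = 0.01, min_replicates = 3)
  expect_true("S2" %in% cls5$strains)
})

test_that("dropout grid enumerates conditions and guards its inputs", {
  cfg <- synth_config(n_strains = 3, n_args = 2, seed = 6)
  fit <- combine_fitness(setNames(c(1, 1.01, 0.99), sprintf("ST%02d", 1:3)),
                         gen_effect_matrix(cfg)$matrix)
  fit$sd <- 0
  sc <- sim_config(pop_size = 300, generations = 30, replicates = 4,
                   min_replicates_persist = 2, seed = 11)
  grid <- dropout_grid(fit, sc)
  expect_equal(nrow(grid$conditions), (1 + 3) * (1 + 2))
  expect_true(all(grid$conditions$n_persisted_strains >= 1))

  long <- dropout_long(grid)
  expect_true(all(c("dropped_strain", "dropped_arg", "strain_id",
                    "arg_id", "mean_final_freq") %in% names(long)))
  expect_error(dropout_grid(fit, sc, drop_args = "VECTOR"),
               "vector control")
  expect_error(dropout_grid(fit, sc, drop_strains = "ZZ"),
               "unknown strain")

  # derived per-condition seeds: the same condition in a smaller grid
  # gives identical results
  grid_sub <- dropout_grid(fit, sc, drop_strains = "ST01",
                           drop_args = character(0))
  i_full <- which(grid$conditions$dropped_strain == "ST01" &
                    is.na(grid$conditions$dropped_arg))
  i_sub <- which(grid_sub$conditions$dropped_strain == "ST01" &
                   is.na(grid_sub$conditions$dropped_arg))
  expect_equal(grid$mean_final[[i_full]], grid_sub$mean_final[[i_sub]])
})
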
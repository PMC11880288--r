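# EO / GLEO mechanics: encoding, fitness, pool, update equations, exemplar
# construction, elitism, and the grid-search baseline.

sphere <- function(x) sum(x^2)

test_that("decoding maps genes onto masks and integer hyperparameters", {
  space <- search_space("FS_HT")
  base <- rfr_default_config()

  v <- c(rep(0.6, 12), 0, 0.5, 1, 0.25)
  dec <- decode_solution(v, space, base)
  expect_true(all(dec$mask))
  expect_equal(dec$config$n_trees, 200)   # gene 0 -> range low
  expect_equal(dec$config$m_trees, round(1 + 0.5 * 11))
  expect_equal(dec$config$min_leaf_size, 10)  # gene 1 -> range high
  expect_equal(dec$config$n_splits, 125)

  v[13] <- 1
  expect_equal(decode_solution(v, space, base)$config$n_trees, 1500)

  # a flag of exactly 0.5 is NOT selected (strict >)
  v2 <- c(rep(0.5, 12), rep(0.5, 4))
  expect_false(any(decode_solution(v2, space, base)$mask))

  fs_space <- search_space("FS")
  dec_fs <- decode_solution(rep(0.7, 12), fs_space, base)
  expect_true(all(dec_fs$mask))
  expect_identical(dec_fs$config, base)

  ht_space <- search_space("HT")
  dec_ht <- decode_solution(rep(0.5, 4), ht_space, base)
  expect_true(all(dec_ht$mask))
  expect_error(decode_solution(rep(0.5, 5), ht_space, base), "match")
})

test_that("search space dimensions and range overrides behave", {
  expect_equal(search_space("FS")$dim, 12)
  expect_equal(search_space("HT")$dim, 4)
  expect_equal(search_space("FS_HT")$dim, 16)
  wide <- search_space("HT", hp_ranges = list(n_splits = c(100, 50000)))
  expect_equal(wide$hp_ranges$n_splits, c(100, 50000))
  expect_error(search_space("HT", hp_ranges = list(n_trees = c(5, 5))),
               "range")
})

test_that("fitness penalizes empty masks, prefers informative features, and is deterministic", {
  ds <- make_feature_dataset(300, informative_idx = 1, noise_sd = 0.05,
                             seed = 13)
  space <- search_space("FS")
  base <- rfr_config(n_trees = 60, seed = 1)
  fn <- make_rfr_fitness(ds$table, space, base, inner_seed = 5)

  expect_equal(fn(rep(0.1, 12)), 1e9)

  informative_only <- c(1, rep(0, 11))
  noise_only <- c(0, 0, 0, 0.9, rep(0, 8))
  wins <- sum(vapply(1:10, function(s) {
    fn2 <- make_rfr_fitness(ds$table, space, base, inner_seed = s)
    fn2(informative_only) < fn2(noise_only)
  }, logical(1)))
  expect_gte(wins, 9)

  v <- runif(12)
  expect_identical(fn(v), fn(v))
})

test_that("population initialization is uniform, seeded, and pool-sorted", {
  st <- init_population(10, 16, sphere, seed = 4)
  expect_equal(dim(st$population), c(10, 16))
  expect_true(all(st$population >= 0 & st$population <= 1))
  expect_equal(st$pool_fitness, sort(st$pool_fitness))
  expect_equal(st$pool[5, ], colMeans(st$pool[1:4, ]))
  st2 <- init_population(10, 16, sphere, seed = 4)
  expect_identical(st$population, st2$population)
})

test_that("the equilibrium pool is elitist and averages its four members", {
  pop <- matrix(seq(0.1, 1, length.out = 5 * 3), 5, 3)
  fit <- c(3, 1, 5, 2, 4)
  p <- mmgtorque:::update_pool(NULL, numeric(0), pop, fit)
  expect_equal(p$fitness, c(1, 2, 3, 4))
  expect_equal(p$pool[1, ], pop[2, ])
  expect_equal(p$pool[5, ], colMeans(pop[c(2, 4, 1, 5), ]))

  # a worse batch leaves the pool unchanged
  worse <- matrix(runif(15), 5, 3)
  p2 <- mmgtorque:::update_pool(p$pool[1:4, ], p$fitness, worse,
                                rep(100, 5))
  expect_equal(p2$fitness, p$fitness)
  expect_equal(p2$pool, p$pool)
})

test_that("the final-iteration update collapses onto the pool candidate", {
  set.seed(6)
  pop <- matrix(runif(12), 3, 4)
  pool <- rbind(matrix(runif(16), 4, 4),
                colMeans(matrix(runif(16), 4, 4)))
  set.seed(7)
  out <- mmgtorque:::eo_update_positions(pop, pool, iter = 50, max_iter = 50)
  set.seed(7)
  picks <- t(vapply(1:3, function(i) {
    j <- sample.int(5, 1); runif(4); runif(4); runif(1); runif(1)
    pool[j, ]
  }, numeric(4)))
  expect_equal(out, picks, tolerance = 1e-15)
})

test_that("a converged population at the equilibrium point stays put", {
  # at the optimum encoding (all genes 0) the mixing and generation terms
  # both vanish, so the update is an exact fixed point
  pool <- matrix(0, 5, 4)
  pop <- matrix(0, 3, 4)
  set.seed(8)
  out <- mmgtorque:::eo_update_positions(pop, pool, iter = 10, max_iter = 100)
  expect_equal(out, pop, tolerance = 1e-15)
})

test_that("one seeded EO update matches the straight-line oracle to 1e-12", {
  set.seed(11)
  pop <- matrix(runif(3 * 5), 3, 5)
  fit <- apply(pop, 1, sphere)
  pool4 <- pop[order(fit)[c(1, 2, 3, 1)], ]
  pool <- rbind(pool4, colMeans(pool4))
  for (iter in c(1, 17, 60)) {
    set.seed(1000 + iter)
    got <- mmgtorque:::eo_update_positions(pop, pool, iter, max_iter = 100)
    set.seed(1000 + iter)
    want <- oracle_eo_update(pop, pool, iter, max_iter = 100)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("the exemplar honours the learning probability at its boundaries", {
  st <- init_population(5, 6, sphere, seed = 14)
  set.seed(15)
  ex1 <- gleo_exemplar(st, 1, pl_i = 1)
  # every gene must come from some population member's same dimension
  for (d in 1:6) expect_true(ex1[d] %in% st$population[, d])

  set.seed(16)
  ex0 <- gleo_exemplar(st, 1, pl_i = 0)
  from_pool <- vapply(1:6, function(d) ex0[d] %in% st$pool[, d], logical(1))
  # all but (at most) the one forced dimension come from the pool
  expect_gte(sum(from_pool), 5)
})

test_that("two-way tournaments always return the lower-fitness member", {
  st <- init_population(5, 4, sphere, seed = 17)
  # exhaustively: for every pair, the winner used by the exemplar rule
  for (a in 1:4) for (b in (a + 1):5) {
    pair <- c(a, b)
    winner <- pair[which.min(st$fitness[pair])]
    expect_equal(st$fitness[winner], min(st$fitness[pair]))
  }
  # with pl = 1 every gene comes from a tournament winner, and the unique
  # worst member can never win a tournament
  worst <- which.max(st$fitness)
  set.seed(18)
  for (k in 1:20) {
    ex <- gleo_exemplar(st, 1, pl_i = 1)
    for (d in 1:4) {
      expect_false(ex[d] == st$population[worst, d])
    }
  }
})

test_that("GLEO with a degenerate ramp matches EO updates distributionally", {
  # with pl = 0 the exemplar is pool-per-dimension (plus one forced gene);
  # each coordinate of the EO pull target has the same marginal law, so the
  # updated first coordinates should be indistinguishable over many seeds
  st <- init_population(8, 16, sphere, seed = 19)
  n_rep <- 400
  eo_first <- numeric(n_rep)
  gleo_first <- numeric(n_rep)
  for (k in seq_len(n_rep)) {
    set.seed(20000 + k)
    eo_first[k] <- mmgtorque:::eo_update_positions(
      st$population, st$pool, iter = 5, max_iter = 100
    )[1, 1]
    set.seed(50000 + k)
    ex <- t(vapply(1:8, function(i) gleo_exemplar(st, i, 0),
                   numeric(16)))
    gleo_first[k] <- mmgtorque:::eo_update_positions(
      st$population, st$pool, iter = 5, max_iter = 100, exemplars = ex
    )[1, 1]
  }
  expect_gt(suppressWarnings(ks.test(eo_first, gleo_first))$p.value, 0.01)
})

test_that("traces are non-increasing and the optimizer is seed-reproducible", {
  for (alg in c("EO", "GLEO")) {
    res <- eo_optimize(sphere, dim = 8, algorithm = alg, n_pop = 6,
                       max_iter = 30, seed = 21)
    expect_length(res$trace, 30)
    expect_true(all(diff(res$trace) <= 1e-15))
    res2 <- eo_optimize(sphere, dim = 8, algorithm = alg, n_pop = 6,
                        max_iter = 30, seed = 21)
    expect_identical(res$trace, res2$trace)
    expect_true(all(res$state$population >= 0 & res$state$population <= 1))
  }
  one <- eo_optimize(sphere, dim = 4, max_iter = 1, seed = 1)
  expect_length(one$trace, 1)
})

test_that("grid search returns the exhaustive optimum of its grid", {
  ds <- make_feature_dataset(200, informative_idx = c(1L, 2L),
                             noise_sd = 0.05, seed = 22)
  grid <- list(n_trees = c(30, 60), m_trees = c(2, 6),
               min_leaf_size = c(2), n_splits = c(150))
  run <- grid_search_ht(ds$table, grid = grid, seed = 3)
  expect_equal(length(run$grid_fitness), 4)
  expect_equal(run$best_fitness, min(run$grid_fitness))
  expect_equal(run$trace$best_rmse, cummin(run$grid_fitness))
  expect_true(run$best_config$n_trees %in% grid$n_trees)
  expect_true(run$best_config$m_trees %in% grid$m_trees)

  single <- grid_search_ht(ds$table,
                           grid = list(n_trees = 40, m_trees = 3,
                                       min_leaf_size = 4, n_splits = 120),
                           seed = 3)
  expect_equal(single$best_config$n_trees, 40)
  expect_equal(single$best_config$m_trees, 3)
  expect_equal(single$best_config$min_leaf_size, 4)
  expect_equal(single$best_config$n_splits, 120)
})

test_that("a full wrapper run produces a coherent result object", {
  ds <- make_feature_dataset(250, seed = 23)
  run <- run_optimizer(ds$table, "GLEO", "FS",
                       base_config = rfr_config(n_trees = 40, seed = 1),
                       n_pop = 4, max_iter = 3, seed = 9)
  expect_s3_class(run, "gleo_run")
  expect_equal(nrow(run$trace), 3)
  expect_true(all(diff(run$trace$best_rmse) <= 1e-15))
  expect_true(all(run$best_mask %in% c(
    "RMS", "HighBand", "LowerBand", "Tremor", "SPFlx", "MDF",
    "SPC", "SPsp", "MPF", "ZCR", "Mobility", "SPFlt"
  )))
  expect_equal(run$n_train + run$n_test, 250)

  run2 <- run_optimizer(ds$table, "GLEO", "FS",
                        base_config = rfr_config(n_trees = 40, seed = 1),
                        n_pop = 4, max_iter = 3, seed = 9)
  expect_identical(run2$trace, run$trace)
  expect_identical(run2$best_mask, run$best_mask)

  g <- glance(run)
  expect_equal(g$test_rmse, run$test_metrics$rmse)
  td <- tidy(run)
  expect_equal(nrow(td), 3)
  expect_s3_class(ggplot2::autoplot(run), "ggplot")
})
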
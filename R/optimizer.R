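# Equilibrium Optimizer (EO) and General Learning Equilibrium Optimizer
# (GLEO) over a unified [0,1]^dim encoding of feature flags and
# hyperparameter genes, with wrapper fitness = validation RMSE of a
# random-forest torque model. Three run modes: FS (feature selection only),
# HT (hyperparameter tuning only), FS_HT (joint).
#
# EO constants follow the canonical algorithm: a1 = 2, a2 = 1, GP = 0.5,
# V = 1. The equilibrium pool holds the four best solutions ever seen plus
# their elementwise mean (elitist memory), which makes the best-so-far trace
# non-increasing by construction.

EO_CONSTANTS <- list(a1 = 2, a2 = 1, GP = 0.5, V = 1)
EMPTY_MASK_PENALTY <- 1e9

#' Search space for the optimizer
#'
#' @param mode One of `"FS_HT"` (joint, 16 genes), `"FS"` (12 feature flags),
#'   `"HT"` (4 hyperparameter genes).
#' @param hp_ranges Named list of `c(lo, hi)` integer ranges for the four
#'   hyperparameters. Defaults: `n_trees` 200-1500, `m_trees` 1-12,
#'   `min_leaf_size` 1-10, `n_splits` 100-200. Override freely — e.g. widen
#'   `n_splits` to effectively uncap tree depth.
#' @return A list of class `search_space` with the derived `dim`.
#' @export
search_space <- function(mode = c("FS_HT", "FS", "HT"), hp_ranges = NULL) {
  mode <- match.arg(mode)
  defaults <- list(
    n_trees = c(200, 1500), m_trees = c(1, 12),
    min_leaf_size = c(1, 10), n_splits = c(100, 200)
  )
  if (!is.null(hp_ranges)) defaults[names(hp_ranges)] <- hp_ranges
  for (nm in names(defaults)) {
    r <- defaults[[nm]]
    if (length(r) != 2 || r[1] >= r[2]) abort(sprintf("bad range for `%s`", nm))
  }
  dim <- switch(mode, FS = 12L, HT = 4L, FS_HT = 16L)
  structure(list(mode = mode, n_features = 12L, hp_ranges = defaults,
                 dim = dim),
            class = "search_space")
}

#' Decode a solution vector into a feature mask and configuration
#'
#' Feature flag genes select a feature when strictly greater than 0.5.
#' Hyperparameter genes map linearly onto their integer range:
#' `round(lo + gene * (hi - lo))`. In FS mode the caller-supplied
#' `base_config` is returned unchanged; in HT mode all 12 features are
#' selected.
#'
#' @param genes Numeric vector in `[0,1]^dim`.
#' @param space A [search_space()].
#' @param base_config The fixed [rfr_config()] used in FS mode (also donates
#'   the forest seed in every mode).
#' @return A list with `mask` (logical, length 12) and `config`
#'   ([rfr_config()]).
#' @export
decode_solution <- function(genes, space, base_config = rfr_default_config()) {
  if (length(genes) != space$dim) abort("gene length does not match space")
  genes <- pmin(pmax(genes, 0), 1)
  mask <- rep(TRUE, 12)
  cfg <- base_config
  if (space$mode %in% c("FS", "FS_HT")) {
    mask <- genes[1:12] > 0.5
  }
  if (space$mode %in% c("HT", "FS_HT")) {
    hp_genes <- genes[(space$dim - 3L):space$dim]
    vals <- purrr::imap_dbl(space$hp_ranges, function(r, nm) {
      g <- hp_genes[match(nm, names(space$hp_ranges))]
      round(r[1] + g * (r[2] - r[1]))
    })
    cfg <- rfr_config(
      n_trees = vals[["n_trees"]], m_trees = vals[["m_trees"]],
      min_leaf_size = vals[["min_leaf_size"]], n_splits = vals[["n_splits"]],
      seed = base_config$seed
    )
  }
  list(mask = mask, config = cfg)
}

#' Wrapper fitness: inner-validation RMSE of the decoded model
#'
#' Builds a fitness closure over the training subset. The training rows are
#' split once (seeded, 80/20) into an inner fit/validation pair that stays
#' fixed for the whole run; each candidate is decoded, its forest trained on
#' the inner 80% with a run-fixed forest seed, and the RMSE on the inner 20%
#' returned. An empty feature mask short-circuits to a large penalty
#' (`1e9`). Fitness is therefore deterministic given the candidate and the
#' run seeds, and measures generalization rather than training fit.
#'
#' @param train_table The training-subset feature table.
#' @param space A [search_space()].
#' @param base_config Fixed configuration for FS mode.
#' @param inner_seed Integer seed fixing the inner split and forest seed.
#' @param inner_frac Fraction of the training subset used for the inner fit.
#' @return A function `f(genes) -> RMSE`.
#' @export
make_rfr_fitness <- function(train_table, space,
                             base_config = rfr_default_config(),
                             inner_seed = 1L, inner_frac = 0.8) {
  n <- nrow(train_table)
  fit_rows <- withr::with_seed(inner_seed,
                               sort(sample.int(n, round(inner_frac * n))))
  val_rows <- setdiff(seq_len(n), fit_rows)
  forest_seed <- derive_seed(inner_seed, 101)
  fit_tab <- train_table[fit_rows, , drop = FALSE]
  val_tab <- train_table[val_rows, , drop = FALSE]
  function(genes) {
    dec <- decode_solution(genes, space, base_config)
    if (!any(dec$mask)) return(EMPTY_MASK_PENALTY)
    cfg <- dec$config
    cfg$seed <- forest_seed
    fit <- rfr_train(fit_tab, dec$mask, cfg)
    metric_rmse(val_tab$Torque, predict(fit, val_tab))
  }
}

# --- population machinery -------------------------------------------------

# Merge the elitist pool with a population and rebuild: rows 1..4 of the
# returned matrix are the four lowest-fitness solutions ever seen (ascending),
# row 5 their elementwise mean.
update_pool <- function(pool, pool_fitness, population, fitness) {
  cand <- rbind(pool, population)
  candf <- c(pool_fitness, fitness)
  ord <- order(candf)[1:min(4, length(candf))]
  best <- cand[ord, , drop = FALSE]
  list(pool = rbind(best, colMeans(best)), fitness = candf[ord])
}

#' Initialize an optimizer state
#'
#' Uniform `[0,1]` genes for `n_pop` solutions, fitness evaluated, and the
#' equilibrium pool (four best + their mean) formed.
#'
#' @param n_pop Population size.
#' @param dim Genome dimension.
#' @param fn Fitness function (minimized).
#' @param seed Integer seed.
#' @return A list of class `eo_state`.
#' @export
init_population <- function(n_pop, dim, fn, seed = 1L) {
  population <- withr::with_seed(seed, matrix(runif(n_pop * dim), nrow = n_pop))
  fitness <- vapply(seq_len(n_pop), function(i) fn(population[i, ]), numeric(1))
  p <- update_pool(NULL, numeric(0), population, fitness)
  structure(
    list(population = population, fitness = fitness,
         pool = p$pool, pool_fitness = p$fitness,
         iter = 0L, n_pop = n_pop, dim = dim,
         constants = EO_CONSTANTS),
    class = "eo_state"
  )
}

# One position update for the whole population. RNG draw order per solution
# i (documented so an independent oracle can replay it):
#   1. pool index j = sample.int(5, 1)      [EO only; GLEO passes exemplars]
#   2. lambda = runif(dim)
#   3. r = runif(dim)
#   4. r1 = runif(1); r2 = runif(1)
# Update: t = (1 - iter/max_iter)^(a2 * iter/max_iter);
#         F = a1 * sign(r - 0.5) * (exp(-lambda * t) - 1);
#         GCP = 0.5 * r1 if r2 >= GP else 0;  G = GCP * (Ceq - lambda*C) * F;
#         C' = Ceq + (C - Ceq)*F + G/(lambda*V) * (1 - F), clipped to [0,1].
# At iter == max_iter, t = 0 forces F = 0 and G = 0, so C' = Ceq exactly.
eo_update_positions <- function(population, pool, iter, max_iter,
                                exemplars = NULL, constants = EO_CONSTANTS) {
  n_pop <- nrow(population)
  dim <- ncol(population)
  t_iter <- (1 - iter / max_iter)^(constants$a2 * iter / max_iter)
  out <- population
  for (i in seq_len(n_pop)) {
    ceq <- if (is.null(exemplars)) pool[sample.int(5, 1), ] else exemplars[i, ]
    lambda <- runif(dim)
    r <- runif(dim)
    r1 <- runif(1)
    r2 <- runif(1)
    f <- constants$a1 * sign(r - 0.5) * (exp(-lambda * t_iter) - 1)
    gcp <- if (r2 >= constants$GP) 0.5 * r1 else 0
    g <- gcp * (ceq - lambda * population[i, ]) * f
    cnew <- ceq + (population[i, ] - ceq) * f +
      g / (lambda * constants$V) * (1 - f)
    out[i, ] <- pmin(pmax(cnew, 0), 1)
  }
  out
}

#' Per-solution general-learning exemplar
#'
#' Builds the exemplar a GLEO solution relaxes towards. For each dimension,
#' with probability `pl_i` the gene is taken from the winner (lower fitness)
#' of a two-way tournament between two distinct random population members;
#' otherwise from a uniformly chosen member of the 5-candidate equilibrium
#' pool. If no dimension drew a tournament gene, one random dimension is
#' forced to, so every exemplar carries at least some peer information.
#'
#' @param state An `eo_state`.
#' @param i Solution index (unused in the draw itself; kept for clarity of
#'   the per-solution contract).
#' @param pl_i Learning probability for this solution.
#' @return Numeric exemplar vector of length `state$dim`.
#' @export
gleo_exemplar <- function(state, i, pl_i) {
  dim <- state$dim
  exemplar <- numeric(dim)
  from_tournament <- logical(dim)
  for (d in seq_len(dim)) {
    if (runif(1) < pl_i) {
      pair <- sample.int(state$n_pop, 2)
      winner <- pair[which.min(state$fitness[pair])]
      exemplar[d] <- state$population[winner, d]
      from_tournament[d] <- TRUE
    } else {
      exemplar[d] <- state$pool[sample.int(5, 1), d]
    }
  }
  if (!any(from_tournament)) {
    d0 <- sample.int(dim, 1)
    pair <- sample.int(state$n_pop, 2)
    winner <- pair[which.min(state$fitness[pair])]
    exemplar[d0] <- state$population[winner, d0]
  }
  exemplar
}

# Exponential comprehensive-learning ramp: solution 1 learns rarely
# (pl = 0.05), solution N almost always (pl = 0.5).
pl_ramp <- function(n_pop) {
  if (n_pop == 1) return(0.05)
  i <- seq_len(n_pop)
  0.05 + 0.45 * (exp(10 * (i - 1) / (n_pop - 1)) - 1) / (exp(10) - 1)
}

#' One EO / GLEO iteration
#'
#' Updates every solution towards a pool candidate (EO) or its
#' general-learning exemplar (GLEO), re-evaluates fitness, and merges the
#' results into the elitist equilibrium pool.
#'
#' @param state An `eo_state`.
#' @param fn Fitness function.
#' @param max_iter Total iteration budget (enters the time decay).
#' @param algorithm `"EO"` or `"GLEO"`.
#' @param pl Per-solution learning probabilities (GLEO; default the
#'   exponential ramp).
#' @return The updated `eo_state` (with `iter` incremented).
#' @export
eo_step <- function(state, fn, max_iter, algorithm = c("EO", "GLEO"),
                    pl = pl_ramp(state$n_pop)) {
  algorithm <- match.arg(algorithm)
  iter <- state$iter + 1L
  exemplars <- NULL
  if (algorithm == "GLEO") {
    exemplars <- t(vapply(
      seq_len(state$n_pop),
      function(i) gleo_exemplar(state, i, pl[i]),
      numeric(state$dim)
    ))
  }
  population <- eo_update_positions(state$population, state$pool, iter,
                                    max_iter, exemplars, state$constants)
  fitness <- vapply(seq_len(state$n_pop),
                    function(i) fn(population[i, ]), numeric(1))
  p <- update_pool(state$pool[1:4, , drop = FALSE], state$pool_fitness,
                   population, fitness)
  state$population <- population
  state$fitness <- fitness
  state$pool <- p$pool
  state$pool_fitness <- p$fitness
  state$iter <- iter
  state
}

#' Minimize an arbitrary fitness function with EO or GLEO
#'
#' Generic driver over `[0,1]^dim`: initialize, iterate `max_iter` steps,
#' return the best solution ever seen and the per-iteration best-fitness
#' trace (non-increasing by elitism).
#'
#' @param fn Fitness function mapping a `[0,1]^dim` vector to a scalar.
#' @param dim Genome dimension.
#' @param algorithm `"EO"` or `"GLEO"`.
#' @param n_pop Population size (default 10).
#' @param max_iter Iteration budget (default 100).
#' @param seed Integer seed.
#' @return A list with `best`, `best_fitness`, `trace` (length `max_iter`),
#'   and the final `state`.
#' @export
#' @examples
#' sphere <- function(x) sum((x - 0.3)^2)
#' res <- eo_optimize(sphere, dim = 4, algorithm = "GLEO",
#'                    max_iter = 50, seed = 1)
#' res$best_fitness
eo_optimize <- function(fn, dim, algorithm = c("EO", "GLEO"), n_pop = 10L,
                        max_iter = 100L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  state <- init_population(n_pop, dim, fn, seed = derive_seed(seed, 1))
  trace <- numeric(max_iter)
  pl <- pl_ramp(n_pop)
  withr::with_seed(derive_seed(seed, 2), {
    for (k in seq_len(max_iter)) {
      state <- eo_step(state, fn, max_iter, algorithm, pl)
      trace[k] <- state$pool_fitness[1]
    }
  })
  list(best = state$pool[1, ], best_fitness = state$pool_fitness[1],
       trace = trace, state = state)
}

#' Run the full wrapper optimization on a feature table
#'
#' Splits the table (histogram-binned stratified 70/30 unless `split` is
#' given), optimizes the chosen mode's encoding against inner-validation
#' RMSE on the training subset, decodes the best solution, retrains on the
#' full training subset, and evaluates on the held-out test subset.
#'
#' @param table Feature table (12 features + `Torque` on [0, 1]).
#' @param algorithm `"GLEO"` (default) or `"EO"`.
#' @param mode `"FS_HT"`, `"FS"`, or `"HT"`.
#' @param base_config Fixed [rfr_config()] used in FS mode and as the seed
#'   donor elsewhere.
#' @param hp_ranges Optional hyperparameter range overrides (see
#'   [search_space()]).
#' @param n_pop Population size.
#' @param max_iter Iteration budget.
#' @param seed Master seed for this run (split, initialization, search and
#'   final forest all derive from it).
#' @param split Optional list with `train` and `test` row indices; when
#'   supplied, the internal split is skipped.
#' @param spec A [split_spec()] for the internal split.
#' @return An object of class `gleo_run`: best mask/config, trace tibble,
#'   train/test metrics. Supports [tidy()], [glance()] and
#'   [ggplot2::autoplot()].
#' @export
run_optimizer <- function(table, algorithm = c("GLEO", "EO"),
                          mode = c("FS_HT", "FS", "HT"),
                          base_config = rfr_default_config(),
                          hp_ranges = NULL, n_pop = 10L, max_iter = 100L,
                          seed = 1L, split = NULL, spec = split_spec()) {
  algorithm <- match.arg(algorithm)
  mode <- match.arg(mode)
  space <- search_space(mode, hp_ranges)
  if (is.null(split)) {
    spec$seed <- derive_seed(seed, 11)
    split <- stratified_binned_split(table, spec)
  }
  train_tab <- table[split$train, , drop = FALSE]
  fn <- make_rfr_fitness(train_tab, space, base_config,
                         inner_seed = derive_seed(seed, 22))
  res <- eo_optimize(fn, space$dim, algorithm, n_pop, max_iter,
                     seed = derive_seed(seed, 33))
  dec <- decode_solution(res$best, space, base_config)
  final_cfg <- dec$config
  final_cfg$seed <- derive_seed(seed, 44)
  fit <- rfr_train(train_tab, dec$mask, final_cfg)
  structure(
    list(
      algorithm = algorithm, mode = mode, seed = as.integer(seed),
      best_vector = res$best, best_fitness = res$best_fitness,
      best_mask = MMG_FEATURES[dec$mask], best_config = final_cfg,
      trace = tibble::tibble(iter = seq_along(res$trace),
                             best_rmse = res$trace),
      train_metrics = rfr_evaluate(fit, train_tab),
      test_metrics = rfr_evaluate(fit, table, split$test),
      n_train = length(split$train), n_test = length(split$test),
      fit = fit
    ),
    class = "gleo_run"
  )
}

#' @export
print.gleo_run <- function(x, ...) {
  m <- x$test_metrics
  cat(sprintf(
    "<%s-RFR-%s run> %d iterations, best validation RMSE %.4f\n",
    x$algorithm, gsub("_", "-", x$mode), nrow(x$trace), x$best_fitness
  ))
  cat(sprintf("  selected features (%d/12): %s\n", length(x$best_mask),
              paste(x$best_mask, collapse = ", ")))
  cat(sprintf(
    "  config: Ntrees=%d mTrees=%d MinLeafSize=%d Nsplits=%s\n",
    x$best_config$n_trees, x$best_config$m_trees,
    x$best_config$min_leaf_size,
    if (is.finite(x$best_config$n_splits)) x$best_config$n_splits else "Inf"
  ))
  cat(sprintf("  test: RMSE=%.4f R2=%.4f slope=%.4f (n=%d)\n",
              m$rmse, m$r2, m$slope, m$n))
  invisible(x)
}

#' Exhaustive grid-search baseline for hyperparameter tuning
#'
#' Evaluates every configuration on the Cartesian grid with the same
#' inner-validation fitness the metaheuristics use, then retrains the best
#' on the full training subset and evaluates on the test subset.
#'
#' @param table Feature table.
#' @param grid Named list of candidate values per hyperparameter.
#' @param base_config Seed-donor configuration.
#' @param seed Master seed (split, inner split, forests).
#' @param split,spec As in [run_optimizer()].
#' @return A `gleo_run` (algorithm `"GRID"`, mode `"HT"`); its trace is the
#'   running best over the grid evaluation order.
#' @export
grid_search_ht <- function(table,
                           grid = list(n_trees = c(200, 850, 1500),
                                       m_trees = c(1, 4, 8, 12),
                                       min_leaf_size = c(1, 5, 10),
                                       n_splits = c(100, 200)),
                           base_config = rfr_default_config(), seed = 1L,
                           split = NULL, spec = split_spec()) {
  if (is.null(split)) {
    spec$seed <- derive_seed(seed, 11)
    split <- stratified_binned_split(table, spec)
  }
  train_tab <- table[split$train, , drop = FALSE]
  # HT space whose ranges cover the grid, so grid points decode exactly.
  ranges <- purrr::map(grid, function(v) range(c(v, v[1] + 1)))
  space <- search_space("HT", hp_ranges = ranges)
  fn <- make_rfr_fitness(train_tab, space, base_config,
                         inner_seed = derive_seed(seed, 22))
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  genes_for <- function(row) {
    vapply(names(space$hp_ranges), function(nm) {
      r <- space$hp_ranges[[nm]]
      (row[[nm]] - r[1]) / (r[2] - r[1])
    }, numeric(1))
  }
  fits <- vapply(seq_len(nrow(combos)),
                 function(k) fn(genes_for(combos[k, ])), numeric(1))
  best_k <- which.min(fits)
  best_genes <- genes_for(combos[best_k, ])
  dec <- decode_solution(best_genes, space, base_config)
  final_cfg <- dec$config
  final_cfg$seed <- derive_seed(seed, 44)
  fit <- rfr_train(train_tab, dec$mask, final_cfg)
  structure(
    list(
      algorithm = "GRID", mode = "HT", seed = as.integer(seed),
      best_vector = best_genes, best_fitness = fits[best_k],
      best_mask = MMG_FEATURES[dec$mask], best_config = final_cfg,
      trace = tibble::tibble(iter = seq_along(fits), best_rmse = cummin(fits)),
      train_metrics = rfr_evaluate(fit, train_tab),
      test_metrics = rfr_evaluate(fit, table, split$test),
      n_train = length(split$train), n_test = length(split$test),
      fit = fit,
      grid_fitness = fits
    ),
    class = "gleo_run"
  )
}

#' Evaluate the untuned baseline model on the same split protocol
#'
#' Trains the default-configuration forest on all 12 features over the
#' training subset and reports test metrics — the untuned row the optimized
#' modes are compared against.
#'
#' @inheritParams run_optimizer
#' @return A `gleo_run` (algorithm `"NONE"`, mode `"DEFAULT"`).
#' @export
baseline_rfr <- function(table, base_config = rfr_default_config(),
                         seed = 1L, split = NULL, spec = split_spec()) {
  if (is.null(split)) {
    spec$seed <- derive_seed(seed, 11)
    split <- stratified_binned_split(table, spec)
  }
  train_tab <- table[split$train, , drop = FALSE]
  cfg <- base_config
  cfg$seed <- derive_seed(seed, 44)
  fit <- rfr_train(train_tab, rep(TRUE, 12), cfg)
  structure(
    list(
      algorithm = "NONE", mode = "DEFAULT", seed = as.integer(seed),
      best_vector = numeric(0), best_fitness = NA_real_,
      best_mask = MMG_FEATURES, best_config = cfg,
      trace = tibble::tibble(iter = integer(0), best_rmse = numeric(0)),
      train_metrics = rfr_evaluate(fit, train_tab),
      test_metrics = rfr_evaluate(fit, table, split$test),
      n_train = length(split$train), n_test = length(split$test),
      fit = fit
    ),
    class = "gleo_run"
  )
}
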
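#' Assemble a run configuration
#'
#' Collects the search-space, Harmony Search, training and simulation blocks
#' plus a single master seed from which every module seed is derived
#' deterministically.  `read_run_config()` loads the same structure from a
#' YAML file; every `cmd_*` run archives its resolved configuration beside
#' its outputs.
#'
#' @param space an [hp_space()] (default: a desk-scale shrunken space; the
#'   full-scale study space is `hp_space()`).
#' @param hs named list of [hs_params()] overrides, or `"sample"` entries
#'   resolved by [sample_hs_params()].
#' @param training a [training_config()].
#' @param simulation named list: `n_subjects`, `pieces_per_type`, `fs`,
#'   `duration`, `noise`, `n_train_pool`, `val_fraction`.
#' @param seed master integer seed.
#' @param output_dir directory for run outputs.
#' @return A list of class `run_config`.
#' @export
run_config <- function(space = small_space(),
                       hs = list(),
                       training = training_config(),
                       simulation = list(n_subjects = 10, pieces_per_type = 50,
                                         fs = 20, duration = 10, noise = 0.05,
                                         n_train_pool = 1500,
                                         val_fraction = 0.2),
                       seed = 1L,
                       output_dir = tempfile("hscnn-run-")) {
  sim_defaults <- list(n_subjects = 10, pieces_per_type = 50, fs = 20,
                       duration = 10, noise = 0.05, n_train_pool = 1500,
                       val_fraction = 0.2)
  simulation <- utils::modifyList(sim_defaults, simulation)
  structure(list(space = space, hs = hs, training = training,
                 simulation = simulation, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

# module seeds derived from the master seed, kept below 2^31
derive_seed <- function(seed, module) {
  offsets <- c(simulate = 101L, split = 211L, optimize = 307L,
               evaluate = 401L, objective = 503L)
  (as.integer(seed) * 7919L + offsets[[module]]) %% 2147483587L
}

#' Desk-scale shrunken search space
#'
#' A reduced version of the full-scale space for laptop-sized experiments:
#' the same three axes and odd-kernel parity, but kernel counts up to 16 and
#' dense widths up to 128 so a single CNN training takes well under a second
#' on short synthetic pieces.  The full-scale space remains `hp_space()`.
#'
#' @param cld number of convolutional layers.
#' @return An [hp_space()].
#' @export
small_space <- function(cld = 2L) {
  hp_space(cld = cld, ks_min = 3L, ks_max = 15L, ks_odd = TRUE,
           kc_min = 4L, kc_max = 16L, dlnc_min = 16L, dlnc_max = 128L)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with optional `space`, `hs`, `training`,
#'   `simulation`, `seed` and `output_dir` blocks.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  space <- if (is.null(raw$space)) small_space()
           else do.call(hp_space, raw$space)
  training <- if (is.null(raw$training)) training_config()
              else do.call(training_config, raw$training)
  run_config(space = space,
             hs = if (is.null(raw$hs)) list() else raw$hs,
             training = training,
             simulation = if (is.null(raw$simulation)) list() else raw$simulation,
             seed = if (is.null(raw$seed)) 1L else raw$seed,
             output_dir = if (is.null(raw$output_dir)) tempfile("hscnn-run-")
                          else raw$output_dir)
}

archive_config <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(list(
    space = config$space[setdiff(names(config$space), "class")],
    hs = config$hs,
    training = unclass(config$training),
    simulation = config$simulation,
    seed = config$seed), file.path(dir, "config.yaml"))
}

#' Surrogate objective with a planted optimum
#'
#' A cheap, deterministic stand-in for the CNN recognition-rate objective,
#' used to verify the optimizer: `100 * exp(-sum(((x - target)/scale)^2))`
#' with per-axis scales equal to the axis ranges.  The score is 100 exactly
#' at the target and strictly decreases with each coordinate's distance, so
#' the global argmax is the planted target.
#'
#' @param target an [hp_vector()]: the planted optimum.
#' @param space an [hp_space()] providing the per-axis scales.
#' @return An object of class `surrogate_objective`; call it via
#'   [surrogate_score()] or use `$fn` as an objective for [run_hs()].
#' @export
surrogate_objective <- function(target, space) {
  scales <- c(rep(max(space$ks_max - space$ks_min, 1L), space$cld),
              rep(max(space$kc_max - space$kc_min, 1L), space$cld),
              rep(max(space$dlnc_max - space$dlnc_min, 1L), 2L))
  tvec <- hp_as_integer(target)
  obj <- structure(list(target = target, scales = scales),
                   class = "surrogate_objective")
  obj$fn <- function(hp) surrogate_score(hp, obj)
  obj
}

#' Score a hyperparameter vector under a surrogate objective
#'
#' @param hp an [hp_vector()].
#' @param surrogate a [surrogate_objective()].
#' @return Score in (0, 100]; 100 iff `hp` equals the planted target.
#' @export
surrogate_score <- function(hp, surrogate) {
  d <- (hp_as_integer(hp) - hp_as_integer(surrogate$target)) / surrogate$scales
  100 * exp(-sum(d^2))
}

#' Simulate, split and write a synthetic respiration dataset
#'
#' @param config a [run_config()].
#' @return Invisibly, the split `respiration_dataset`; files are written
#'   under `config$output_dir/dataset`.
#' @export
cmd_simulate <- function(config) {
  sim <- config$simulation
  ds <- generate_dataset(n_subjects = sim$n_subjects,
                         pieces_per_type = sim$pieces_per_type,
                         fs = sim$fs, duration = sim$duration,
                         noise = sim$noise,
                         seed = derive_seed(config$seed, "simulate"))
  ds <- split_dataset(ds, n_train_pool = sim$n_train_pool,
                      val_fraction = sim$val_fraction,
                      seed = derive_seed(config$seed, "split"))
  out <- file.path(config$output_dir, "dataset")
  write_dataset(ds, out)
  archive_config(config, config$output_dir)
  cat(sprintf("wrote %d pieces (%d samples each) to %s\n",
              nrow(ds$signals), ncol(ds$signals), out))
  print(table(label = ds$labels, split = ds$split))
  invisible(ds)
}

resolve_hs_params <- function(config) {
  hs <- config$hs
  sampled <- vapply(c("hmcr", "par", "mpap"),
                    function(f) is.null(hs[[f]]) || identical(hs[[f]], "sample"),
                    logical(1))
  overrides <- hs[!vapply(hs, identical, logical(1), "sample")]
  sample_hs_params(overrides = overrides,
                   seed = derive_seed(config$seed, "optimize"))
}

#' Run the Harmony Search optimization end to end
#'
#' Resolves the HS parameters (sampling HMCR/PAR/MPAP from their grids where
#' not overridden), builds the objective — either the CNN recognition-rate
#' objective on a dataset or the verification surrogate — runs [run_hs()]
#' and writes the best-harmony trajectory log (one row per best-update:
#' iteration, ks/kc/dlnc columns, rate), the full per-iteration trace and a
#' summary document.
#'
#' @param config a [run_config()].
#' @param dataset optional pre-built split dataset; when `NULL` and
#'   `surrogate` is also `NULL`, the dataset is simulated from the config.
#' @param surrogate optional [surrogate_objective()]; when given, no CNN is
#'   trained.
#' @return The [run_hs()] result, invisibly.
#' @export
cmd_optimize <- function(config, dataset = NULL, surrogate = NULL) {
  params <- resolve_hs_params(config)
  if (!is.null(surrogate)) {
    objective <- surrogate$fn
  } else {
    if (is.null(dataset)) dataset <- cmd_simulate(config)
    objective <- make_objective(dataset, config$training,
                                base_seed = derive_seed(config$seed, "objective"))
  }
  params$seed <- derive_seed(config$seed, "optimize")
  res <- run_hs(objective, config$space, params)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res$trajectory,
                     file.path(config$output_dir, "trajectory.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(res$trace, file.path(config$output_dir, "trace.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  archive_config(config, config$output_dir)
  yaml::write_yaml(list(best_hp = format(res$best$hp),
                        best_rate = res$best$r,
                        iterations = res$iterations,
                        evaluations = res$evaluations,
                        termination = res$termination,
                        hmcr = params$hmcr, par = params$par,
                        mpap = params$mpap),
                   file.path(config$output_dir, "summary.yaml"))
  print(res)
  invisible(res)
}

#' Grid-search baseline over explicit per-axis value lists
#'
#' Evaluates the full Cartesian product of the supplied kernel-size,
#' kernel-count and dense-width value lists (each list shared across its
#' layers, the way conventional grid tuning predetermines a handful of
#' values per axis) and reports the best combination together with the
#' evaluation count, which is exactly
#' `|ks|^cld * |kc|^cld * |dlnc|^2`.
#'
#' @param config a [run_config()].
#' @param ks_values,kc_values,dlnc_values integer vectors of admissible
#'   values, all within the configured space bounds.
#' @param objective objective function; defaults to a CNN objective on a
#'   freshly simulated dataset.
#' @param budget refuse grids with more evaluations than this.
#' @return List with `best` (a [harmony()]), `evaluations` (count) and
#'   `results` (data frame of every combination and score).
#' @export
cmd_grid_baseline <- function(config, ks_values, kc_values, dlnc_values,
                              objective = NULL, budget = 1000L) {
  space <- config$space
  check_within <- function(vals, lo, hi, name) {
    if (any(vals < lo | vals > hi))
      stop(sprintf("%s values outside the space bounds [%d, %d]",
                   name, lo, hi))
  }
  check_within(ks_values, space$ks_min, space$ks_max, "ks")
  check_within(kc_values, space$kc_min, space$kc_max, "kc")
  check_within(dlnc_values, space$dlnc_min, space$dlnc_max, "dlnc")
  n_comb <- length(ks_values)^space$cld * length(kc_values)^space$cld *
    length(dlnc_values)^2
  if (n_comb > budget)
    stop(sprintf("grid has %d combinations, above the budget of %d",
                 n_comb, budget))
  if (is.null(objective)) {
    ds <- cmd_simulate(config)
    objective <- make_objective(ds, config$training,
                                base_seed = derive_seed(config$seed, "objective"))
  }
  axes <- c(replicate(space$cld, ks_values, simplify = FALSE),
            replicate(space$cld, kc_values, simplify = FALSE),
            replicate(2L, dlnc_values, simplify = FALSE))
  grid <- do.call(expand.grid, axes)
  scores <- numeric(nrow(grid))
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    row <- as.integer(grid[i, ])
    hp <- hp_vector(ks = row[seq_len(space$cld)],
                    kc = row[space$cld + seq_len(space$cld)],
                    dlnc = row[2L * space$cld + 1:2])
    scores[i] <- objective(hp)
    if (is.null(best) || scores[i] > best$r) best <- harmony(hp, scores[i])
  }
  names(grid) <- c(paste0("ks", seq_len(space$cld)),
                   paste0("kc", seq_len(space$cld)), "dlnc1", "dlnc2")
  list(best = best, evaluations = nrow(grid),
       results = cbind(grid, r = scores))
}

#' Final held-out evaluation of a hyperparameter vector
#'
#' Trains the CNN for `hp` on the full learning pool (train + validation)
#' and reports the recognition rate and per-class confusion matrix on the
#' held-out test split — the final verdict on an optimized architecture.
#'
#' @param config a [run_config()].
#' @param hp an [hp_vector()].
#' @param dataset optional pre-built split dataset (simulated from the
#'   config when `NULL`).
#' @return The `evaluation_result`, invisibly; also written as delimited
#'   text under the output directory.
#' @export
cmd_evaluate <- function(config, hp, dataset = NULL) {
  if (is.null(dataset)) dataset <- cmd_simulate(config)
  pool <- dataset_split(dataset, c("train", "validation"))
  test <- dataset_split(dataset, "test")
  if (length(test$y) == 0L) stop("test split is empty")
  cfg <- config$training
  cfg$seed <- derive_seed(config$seed, "evaluate")
  model <- build_model(hp, input_length = ncol(pool$x),
                       n_classes = nlevels(pool$y),
                       pool_size = cfg$pool_size, seed = cfg$seed)
  model <- train_model(model, pool$x, pool$y, cfg)
  res <- evaluate_model(model, test$x, test$y)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(
    cbind(truth = rownames(res$confusion), as.data.frame(res$confusion)),
    file.path(config$output_dir, "confusion.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  print(res)
  invisible(res)
}

#' Plot the best-so-far recognition-rate curve of a run
#'
#' @param res an [run_hs()] result.
#' @param ... passed to [plot()].
#' @return Invisibly, `res`.
#' @export
plot_trace <- function(res, ...) {
  graphics::plot(res$trace$iteration, res$trace$best_r, type = "s",
                 xlab = "iteration", ylab = "best recognition rate (%)", ...)
  invisible(res)
}
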
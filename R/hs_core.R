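#' Harmony Search engine parameters
#'
#' Bundles the control parameters of the discrete Harmony Search run: the
#' memory capacity (HMS), the memory-recall probability (HMCR), the
#' pitch-adjustment probability (PAR), the maximum pitch-adjustment step
#' (MPAP), the iteration budget and the stagnation threshold `k` that stops
#' the run after `k` consecutive iterations without an improvement of the
#' best harmony.
#'
#' @param hms harmony memory size, at least 2.
#' @param hmcr harmony memory considering ratio in \[0, 1\]: probability a
#'   candidate is recalled from memory instead of drawn at random.
#' @param par pitch adjusting ratio in \[0, 1\]: probability a recalled
#'   candidate is perturbed.
#' @param mpap maximum pitch adjustment proportion, a positive integer: the
#'   largest perturbation step applied to any coordinate.
#' @param max_iterations iteration budget for the improvement loop.
#' @param k stagnation threshold: terminate once the best harmony has not
#'   improved for `k` consecutive iterations.
#' @param seed optional integer seed fixing the whole run.
#' @return An object of class `hs_params`.
#' @export
hs_params <- function(hms = 1000L, hmcr = 0.6, par = 0.7, mpap = 14L,
                      max_iterations = 10000L, k = 200L, seed = NULL) {
  hms <- as.integer(hms); mpap <- as.integer(mpap)
  max_iterations <- as.integer(max_iterations); k <- as.integer(k)
  if (hms < 2L) stop("hms must be >= 2")
  if (hmcr < 0 || hmcr > 1) stop("hmcr must lie in [0, 1]")
  if (par < 0 || par > 1) stop("par must lie in [0, 1]")
  if (mpap < 1L) stop("mpap must be >= 1")
  if (max_iterations < 1L) stop("max_iterations must be >= 1")
  if (k < 1L) stop("k must be >= 1")
  structure(list(hms = hms, hmcr = hmcr, par = par, mpap = mpap,
                 max_iterations = max_iterations, k = k,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "hs_params")
}

#' @export
print.hs_params <- function(x, ...) {
  cat(sprintf("HS parameters: hms=%d hmcr=%.2f par=%.2f mpap=%d budget=%d k=%d\n",
              x$hms, x$hmcr, x$par, x$mpap, x$max_iterations, x$k))
  invisible(x)
}

hmcr_grid <- function() seq(0.50, 0.70, by = 0.05)
par_grid <- function() seq(0.60, 0.80, by = 0.05)
mpap_grid <- function() 10:18

#' Sample Harmony Search parameters from their recommended grids
#'
#' HMCR is drawn uniformly from \{0.50, 0.55, 0.60, 0.65, 0.70\} (0.05 steps),
#' PAR from \{0.60, ..., 0.80\} and MPAP uniformly from the integers 10..18;
#' these ranges keep memory recall frequent without collapsing the search
#' into either a local-maximum trap (high HMCR, small MPAP) or a de facto
#' random search (low HMCR, or very large MPAP).  Remaining fields default to
#' hms = 1000, budget = 10000 iterations and k = 200.
#'
#' @param overrides named list fixing any field instead of sampling it.
#'   Overridden `hmcr`, `par` or `mpap` values must lie on their grids.
#' @param seed optional integer seed for the draw (also stored in the result).
#' @return An [hs_params()] object.
#' @export
sample_hs_params <- function(overrides = list(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pick <- function(name, grid) {
    if (!is.null(overrides[[name]])) {
      v <- overrides[[name]]
      if (!any(abs(grid - v) < 1e-9))
        stop(sprintf("override %s = %s is outside its legal grid {%s}",
                     name, format(v), paste(format(grid), collapse = ", ")))
      v
    } else grid[sample.int(length(grid), 1L)]
  }
  hs_params(
    hms = if (!is.null(overrides$hms)) overrides$hms else 1000L,
    hmcr = pick("hmcr", hmcr_grid()),
    par = pick("par", par_grid()),
    mpap = pick("mpap", mpap_grid()),
    max_iterations = if (!is.null(overrides$max_iterations))
      overrides$max_iterations else 10000L,
    k = if (!is.null(overrides$k)) overrides$k else 200L,
    seed = if (!is.null(seed)) seed else overrides$seed)
}

#' A harmony: hyperparameter vector plus its recognition rate
#'
#' @param hp an [hp_vector()].
#' @param r recognition rate in percent, finite, within \[0, 100\].
#' @return An object of class `harmony`.
#' @export
harmony <- function(hp, r) {
  if (!is.finite(r) || r < 0 || r > 100)
    stop("recognition rate must be finite and within [0, 100]")
  structure(list(hp = hp, r = as.numeric(r)), class = "harmony")
}

#' @export
print.harmony <- function(x, ...) {
  cat(sprintf("%s  R=%.1f%%\n", format(x$hp), x$r))
  invisible(x)
}

# Harmony memory: fixed-capacity pool kept sorted by r descending.  Ties are
# broken by insertion recency (newer first) so behaviour is deterministic.
new_hm <- function(hps, rs) {
  hm <- structure(list(hp = hps, r = as.numeric(rs),
                       stamp = seq_along(rs), counter = length(rs)),
                  class = "harmony_memory")
  hm_sort(hm)
}

hm_sort <- function(hm) {
  ord <- order(-hm$r, -hm$stamp)
  hm$hp <- hm$hp[ord]
  hm$r <- hm$r[ord]
  hm$stamp <- hm$stamp[ord]
  hm
}

hm_size <- function(hm) length(hm$r)

hm_best <- function(hm) harmony(hm$hp[[1L]], hm$r[1L])

hm_worst_r <- function(hm) hm$r[hm_size(hm)]

#' @export
print.harmony_memory <- function(x, ...) {
  cat(sprintf("Harmony memory: %d entries, best R=%.2f%%, worst R=%.2f%%\n",
              hm_size(x), x$r[1L], hm_worst_r(x)))
  invisible(x)
}

#' As a data frame: one row per harmony, sorted by recognition rate
#'
#' @param x a harmony memory.
#' @param row.names,optional,... ignored (data.frame method signature).
#' @return A data.frame with ks/kc/dlnc columns and `r`.
#' @export
as.data.frame.harmony_memory <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  mat <- do.call(rbind, lapply(x$hp, hp_as_integer))
  cld <- (ncol(mat) - 2L) %/% 2L
  colnames(mat) <- c(paste0("ks", seq_len(cld)), paste0("kc", seq_len(cld)),
                     "dlnc1", "dlnc2")
  cbind(as.data.frame(mat), r = x$r)
}

#' Initialize the harmony memory with random architectures
#'
#' Draws `hms` uniformly random hyperparameter vectors, scores each with the
#' objective and returns the memory sorted by recognition rate descending.
#'
#' @param space an [hp_space()].
#' @param objective function mapping an `hp_vector` to a recognition rate in
#'   percent; must return a finite value for every valid vector.
#' @param params an [hs_params()].
#' @return A `harmony_memory` with exactly `params$hms` entries.
#' @export
initialize_hm <- function(space, objective, params) {
  hps <- replicate(params$hms, random_hp(space), simplify = FALSE)
  rs <- vapply(hps, function(hp) {
    r <- tryCatch(objective(hp), error = function(e)
      stop(sprintf("objective failed during initialization on %s: %s",
                   format(hp), conditionMessage(e)), call. = FALSE))
    if (!is.finite(r)) stop(sprintf("objective returned non-finite value on %s",
                                    format(hp)), call. = FALSE)
    as.numeric(r)
  }, numeric(1))
  new_hm(hps, rs)
}

#' Pitch-adjust one discrete coordinate
#'
#' Perturbs `value` by a step drawn uniformly from the signed, nonzero,
#' parity-preserving steps of magnitude at most `mpap` (even steps only on
#' odd-only axes), then clips to the bounds, restoring parity toward the
#' interior.  `mode = "literal"` instead adds exactly `+mpap`, the verbatim
#' update rule, kept for fidelity experiments; unchecked, it drifts every
#' coordinate toward its upper bound.
#'
#' @param value current coordinate value (within bounds and parity).
#' @param mpap maximum step magnitude, a positive integer.
#' @param lower,upper inclusive axis bounds.
#' @param odd if `TRUE` the axis admits odd values only.
#' @param mode `"signed"` (default) or `"literal"`.
#' @param delta optional forced step, overriding the random draw (used in
#'   tests and worked examples).
#' @return The adjusted integer value, always admissible.
#' @export
pitch_adjust <- function(value, mpap, lower, upper, odd = FALSE,
                         mode = c("signed", "literal"), delta = NULL) {
  mode <- match.arg(mode)
  if (is.null(delta)) {
    if (mode == "literal") {
      delta <- mpap
    } else {
      mags <- if (odd) seq_len(mpap %/% 2L) * 2L else seq_len(mpap)
      if (length(mags) == 0L)
        stop("internal error: no admissible pitch-adjustment step ",
             "(mpap too small for the axis parity)")
      steps <- c(-mags, mags)
      delta <- steps[sample.int(length(steps), 1L)]
    }
  }
  out <- as.integer(value + delta)
  if (out > upper) out <- as.integer(upper)
  if (out < lower) out <- as.integer(lower)
  if (odd && out %% 2L == 0L) {
    # restore parity stepping toward the interior of the interval
    out <- if (out >= upper) out - 1L else out + 1L
    if (out < lower) out <- out + 2L
  }
  out
}

#' Propose a new harmony from memory recall, pitch adjustment or random draw
#'
#' With probability `hmcr` a member of the memory is recalled; that recalled
#' vector is then, with probability `par`, pitch-adjusted on every coordinate
#' (all kernel sizes, kernel counts and both dense widths), otherwise
#' returned unchanged.  With probability `1 - hmcr` a fresh uniformly random
#' vector is drawn from the space.
#'
#' @param hm a non-empty harmony memory.
#' @param space an [hp_space()].
#' @param params an [hs_params()].
#' @param mode pitch-adjustment mode, see [pitch_adjust()].
#' @return An `hp_vector` that always passes [validate_hp()].
#' @export
create_new_harmony <- function(hm, space, params, mode = "signed") {
  if (hm_size(hm) == 0L) stop("harmony memory is empty")
  if (stats::runif(1) < params$hmcr) {
    hp <- hm$hp[[sample.int(hm_size(hm), 1L)]]
    if (stats::runif(1) < params$par) {
      ks <- vapply(hp$ks, pitch_adjust, integer(1), mpap = params$mpap,
                   lower = space$ks_min, upper = space$ks_max,
                   odd = space$ks_odd, mode = mode)
      kc <- vapply(hp$kc, pitch_adjust, integer(1), mpap = params$mpap,
                   lower = space$kc_min, upper = space$kc_max,
                   odd = FALSE, mode = mode)
      dlnc <- vapply(hp$dlnc, pitch_adjust, integer(1), mpap = params$mpap,
                     lower = space$dlnc_min, upper = space$dlnc_max,
                     odd = FALSE, mode = mode)
      hp_vector(ks, kc, dlnc)
    } else {
      hp
    }
  } else {
    random_hp(space)
  }
}

#' Replace-worst update of the harmony memory
#'
#' If the candidate's recognition rate strictly exceeds the current worst
#' rate, the worst harmony is removed, the candidate inserted and the memory
#' re-sorted descending; ties do not replace.
#'
#' @param hm a harmony memory at capacity.
#' @param candidate a [harmony()].
#' @return A list with `hm` (the possibly updated memory) and `updated`
#'   (logical flag).
#' @export
update_hm <- function(hm, candidate) {
  n <- hm_size(hm)
  if (candidate$r > hm$r[n]) {
    hm$hp[[n]] <- candidate$hp
    hm$r[n] <- candidate$r
    hm$counter <- hm$counter + 1L
    hm$stamp[n] <- hm$counter
    list(hm = hm_sort(hm), updated = TRUE)
  } else {
    list(hm = hm, updated = FALSE)
  }
}

#' Run the Harmony Search optimization loop
#'
#' Initializes the memory with `hms` random evaluations, then iterates:
#' propose via [create_new_harmony()], evaluate, [update_hm()], and track
#' stagnation.  Whenever the candidate strictly improves on the current best
#' rate the stagnation counter resets; otherwise it grows as the number of
#' iterations since the last best-update, and the run stops early once it
#' reaches `params$k`.  Objective values are cached per hyperparameter tuple
#' so identical architectures are never retrained within a run.
#'
#' @param objective function `hp_vector -> percent in [0, 100]`.
#' @param space an [hp_space()].
#' @param params an [hs_params()]; `params$seed`, when set, makes the whole
#'   run reproducible.
#' @param cache cache objective values by tuple (default `TRUE`).
#' @param mode pitch-adjustment mode, see [pitch_adjust()].
#' @param max_evaluations optional budget on distinct objective evaluations
#'   (trainings), counting the `hms` initialization evaluations; the loop
#'   stops once the budget is exhausted.  `Inf` (default) leaves the run
#'   bounded by `max_iterations` alone.  Cached re-evaluations of an
#'   already-scored tuple do not consume budget.
#' @return An object of class `hs_result`: a list with `best` (the top
#'   harmony), `trace` (one row per iteration: `iteration`, `candidate_r`,
#'   `hm_updated`, `best_updated`, `delta_i`, `best_r`), `trajectory` (one
#'   row per best-update in the layout iteration / ks / kc / dlnc / r),
#'   `termination` (`"stagnation"` or `"budget"`), `evaluations` (count of
#'   distinct objective evaluations) and `params`.
#' @export
run_hs <- function(objective, space, params, cache = TRUE, mode = "signed",
                   max_evaluations = Inf) {
  if (!is.null(params$seed)) set.seed(params$seed)

  cache_env <- new.env(parent = emptyenv())
  n_evals <- 0L
  scored <- function(hp) {
    key <- hp_key(hp)
    if (cache && !is.null(cache_env[[key]])) return(cache_env[[key]])
    r <- objective(hp)
    if (!is.finite(r))
      stop(sprintf("objective returned non-finite value on %s", format(hp)))
    n_evals <<- n_evals + 1L
    if (cache) cache_env[[key]] <- r
    r
  }

  hm <- initialize_hm(space, scored, params)
  best_r <- hm$r[1L]

  n <- params$max_iterations
  trace <- list(iteration = integer(n), candidate_r = numeric(n),
                hm_updated = logical(n), best_updated = logical(n),
                delta_i = integer(n), best_r = numeric(n))
  traj <- list()
  i_prev <- 0L; i_curr <- 0L; delta_i <- 0L
  termination <- "budget"
  executed <- 0L

  for (j in seq_len(n) - 1L) {
    hp_new <- create_new_harmony(hm, space, params, mode = mode)
    r_new <- scored(hp_new)
    upd <- update_hm(hm, harmony(hp_new, r_new))
    hm <- upd$hm
    improved <- r_new > best_r
    if (improved) {
      best_r <- hm$r[1L]
      i_prev <- j; i_curr <- j; delta_i <- 0L
      traj[[length(traj) + 1L]] <- c(iteration = j, hp_as_integer(hp_new),
                                     r = r_new)
    } else {
      i_curr <- j
      delta_i <- i_curr - i_prev
    }
    executed <- executed + 1L
    idx <- j + 1L
    trace$iteration[idx] <- j
    trace$candidate_r[idx] <- r_new
    trace$hm_updated[idx] <- upd$updated
    trace$best_updated[idx] <- improved
    trace$delta_i[idx] <- delta_i
    trace$best_r[idx] <- best_r
    if (delta_i >= params$k) {
      termination <- "stagnation"
      break
    }
    if (n_evals >= max_evaluations) {
      termination <- "budget"
      break
    }
  }

  keep <- seq_len(executed)
  trace <- as.data.frame(lapply(trace, function(col) col[keep]))

  cld <- space$cld
  traj_df <- if (length(traj) > 0L) {
    m <- do.call(rbind, traj)
    colnames(m) <- c("iteration", paste0("ks", seq_len(cld)),
                     paste0("kc", seq_len(cld)), "dlnc1", "dlnc2", "r")
    as.data.frame(m)
  } else {
    empty <- stats::setNames(
      rep(list(numeric(0)), 2L * cld + 4L),
      c("iteration", paste0("ks", seq_len(cld)), paste0("kc", seq_len(cld)),
        "dlnc1", "dlnc2", "r"))
    as.data.frame(empty)
  }

  structure(list(best = hm_best(hm), hm = hm, trace = trace,
                 trajectory = traj_df, termination = termination,
                 iterations = executed, evaluations = n_evals,
                 params = params),
            class = "hs_result")
}

#' @export
print.hs_result <- function(x, ...) {
  cat(sprintf("Harmony Search result: best R=%.2f%% after %d iterations (%s)\n",
              x$best$r, x$iterations, x$termination))
  cat("  best:", format(x$best$hp), "\n")
  cat(sprintf("  %d distinct objective evaluations, %d best-updates\n",
              x$evaluations, nrow(x$trajectory)))
  invisible(x)
}

#' Equal-budget pure random search baseline
#'
#' Evaluates `n` uniformly random hyperparameter vectors and keeps the best;
#' the comparison baseline a Harmony Search run should beat given the same
#' number of objective evaluations.
#'
#' @param objective function `hp_vector -> percent`.
#' @param space an [hp_space()].
#' @param n number of random evaluations.
#' @param seed optional integer seed.
#' @return A list with `best` (a [harmony()]) and `history` (numeric vector
#'   of the `n` scores in draw order).
#' @export
random_search <- function(objective, space, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  history <- numeric(n)
  for (i in seq_len(n)) {
    hp <- random_hp(space)
    r <- objective(hp)
    history[i] <- r
    if (is.null(best) || r > best$r) best <- harmony(hp, r)
  }
  list(best = best, history = history)
}
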
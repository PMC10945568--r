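# Three-phase parameter search. Phase 1: a bounded random walk from the
# seeding values sparsely samples the space (and, with a real evaluator,
# warm-starts each simulation from the previous configuration). Phase 2:
# differential evolution proposes candidates as linear combinations of the
# best points found so far; when a trained surrogate is available, proposals
# whose predicted cost exceeds a threshold skip the true evaluation.
# Phase 3: a surrogate-guided local search refines the best region.

#' Evaluated-candidate population
#'
#' The pool of evaluated points that differential evolution recombines.
#' Holds normalized parameter vectors with their true costs, up to
#' `capacity` members; once full, a new candidate enters only by strictly
#' improving on the worst retained member.
#'
#' @param capacity Maximum number of retained members.
#' @return An object of class `candidate_population`.
#' @export
new_population <- function(capacity = 64L) {
  stopifnot(capacity >= 1)
  structure(list(norm = matrix(numeric(0), 0, 6), cost = numeric(0),
                 capacity = as.integer(capacity)),
            class = "candidate_population")
}

#' @export
print.candidate_population <- function(x, ...) {
  cat(sprintf("Candidate population: %d/%d members", nrow(x$norm), x$capacity))
  if (nrow(x$norm))
    cat(sprintf(", best cost %.4g, worst retained %.4g",
                min(x$cost), max(x$cost)))
  cat("\n")
  invisible(x)
}

#' Insert an evaluated candidate into the population
#'
#' Under capacity the candidate always enters; at capacity it must strictly
#' improve on the worst retained member, which it then evicts. Ties keep the
#' incumbent.
#'
#' @param population A `candidate_population`.
#' @param norm Normalized 6-vector of the candidate.
#' @param cost Its evaluated (true) cost; must be finite.
#' @return List with the updated `population` and logical `accepted`.
#' @export
accept_candidate <- function(population, norm, cost) {
  stopifnot(inherits(population, "candidate_population"))
  if (!is.numeric(cost) || length(cost) != 1L || !is.finite(cost))
    stop("candidate must carry a finite evaluated cost", call. = FALSE)
  if (length(norm) != 6L || any(!is.finite(norm)))
    stop("candidate must carry a finite normalized 6-vector", call. = FALSE)
  n <- nrow(population$norm)
  if (n < population$capacity) {
    population$norm <- rbind(population$norm, as.numeric(norm))
    population$cost <- c(population$cost, cost)
    return(list(population = population, accepted = TRUE))
  }
  worst <- which.max(population$cost)
  if (cost < population$cost[worst]) {
    population$norm[worst, ] <- as.numeric(norm)
    population$cost[worst] <- cost
    return(list(population = population, accepted = TRUE))
  }
  list(population = population, accepted = FALSE)
}

#' One reflected random-walk step in parameter space
#'
#' Perturbs each parameter by a uniform step of up to
#' `step_scale * (upper - lower)` in either direction, reflecting at the
#' boundaries so the walk never leaves the box.
#'
#' @param params Current `water_model_params`, within `bounds`.
#' @param bounds A `parameter_bounds`.
#' @param step_scale Maximum step as a fraction of each parameter's range;
#'   must be in `(0, 1)`.
#' @return The next `water_model_params`.
#' @export
random_walk_step <- function(params, bounds = parameter_bounds(),
                             step_scale = 0.02) {
  if (!is.numeric(step_scale) || length(step_scale) != 1L ||
      step_scale <= 0 || step_scale >= 1)
    stop("'step_scale' must be in (0, 1)", call. = FALSE)
  x <- normalize_params(params, bounds)
  x <- x + runif(6, -step_scale, step_scale)
  x <- ifelse(x < 0, -x, x)
  x <- ifelse(x > 1, 2 - x, x)
  denormalize_params(x, bounds)
}

#' Differential-evolution proposal
#'
#' Generates a pending candidate as a linear combination of population
#' members: mutation `x = x_a + F (x_b - x_c)` with the base `a` drawn from
#' the elite (lowest-cost) fraction and the difference pair `b, c` from the
#' whole population (sourcing difference vectors population-wide preserves
#' search diversity after the elite tier has contracted), then
#' per-coordinate binomial crossover against a randomly chosen population
#' member with probability `CR` (one coordinate always comes from the
#' mutant), then clipping to the unit hypercube.
#'
#' @param population A `candidate_population` with at least 4 members.
#' @param F Differential weight.
#' @param CR Crossover probability.
#' @param elite_fraction Fraction of the population (lowest cost) the
#'   mutation draws from; at least 3 members are always eligible.
#' @return A normalized 6-vector (pending evaluation).
#' @export
de_propose <- function(population, F = 0.7, CR = 0.9, elite_fraction = 0.25) {
  stopifnot(inherits(population, "candidate_population"))
  n <- nrow(population$norm)
  if (n < 4L)
    stop("differential evolution needs at least 4 evaluated members", call. = FALSE)
  elite_n <- min(n, max(3L, ceiling(elite_fraction * n)))
  elite <- order(population$cost)[seq_len(elite_n)]
  a <- sample(elite, 1L)
  bc <- sample(setdiff(seq_len(n), a), 2L)
  mutant <- population$norm[a, ] +
    F * (population$norm[bc[1], ] - population$norm[bc[2], ])
  target <- population$norm[sample.int(n, 1L), ]
  j_rand <- sample.int(6L, 1L)
  take <- runif(6) < CR
  take[j_rand] <- TRUE
  out <- ifelse(take, mutant, target)
  pmin(pmax(out, 0), 1)
}

#' Surrogate-guided refinement proposal
#'
#' Minimizes the surrogate's predicted cost by multi-start coordinate-wise
#' line search in normalized space: restarts from the population's best
#' members, then repeated one-dimensional minimization of each coordinate
#' over `[0, 1]`. The returned candidate is meant to be truly evaluated by
#' the caller; proposals never leave the unit hypercube.
#'
#' @param surrogate A trained `water_mapper`.
#' @param population A non-empty `candidate_population` supplying the
#'   starting points.
#' @param n_restarts Number of elite starting points.
#' @param n_sweeps Coordinate sweeps per start.
#' @return A normalized 6-vector minimizing the surrogate prediction.
#' @export
refine <- function(surrogate, population, n_restarts = 5L, n_sweeps = 3L) {
  stopifnot(inherits(surrogate, "water_mapper"),
            inherits(population, "candidate_population"))
  if (!surrogate$trained)
    stop("refinement requires a trained surrogate", call. = FALSE)
  n <- nrow(population$norm)
  if (n < 1L) stop("population is empty", call. = FALSE)
  starts <- order(population$cost)[seq_len(min(n_restarts, n))]
  best_x <- NULL
  best_pred <- Inf
  for (s in starts) {
    x <- population$norm[s, ]
    for (sweep in seq_len(n_sweeps)) {
      for (j in 1:6) {
        f1 <- function(v) {
          xx <- x; xx[j] <- v
          predict_cost(surrogate, xx)
        }
        opt <- optimize(f1, c(0, 1), tol = 1e-5)
        if (opt$objective < f1(x[j])) x[j] <- opt$minimum
      }
    }
    pred <- predict_cost(surrogate, x)
    if (pred < best_pred) {
      best_pred <- pred
      best_x <- x
    }
  }
  pmin(pmax(best_x, 0), 1)
}

#' Optimization-loop configuration
#'
#' @param rw_steps Random-walk evaluations seeding the population.
#' @param step_scale Random-walk step as a fraction of each range.
#' @param F,CR,elite_fraction Differential-evolution hyperparameters (see
#'   [de_propose()]).
#' @param capacity Population capacity.
#' @param gate_threshold Surrogate skip threshold; `Inf` disables the gate
#'   (no surrogate is trained during differential evolution).
#' @param retrain_every Retrain the surrogate after this many new true
#'   evaluations (or, to replace a poorly fitted network promptly, after
#'   ten times as many proposals even without new evaluations).
#' @param min_gate_r2 Minimum validation R-squared a freshly trained
#'   surrogate must reach before the gate trusts it; a worse fit leaves the
#'   gate in pass-through until the next retraining.
#' @param variant Cost variant, `"ecc"` or `"general"`.
#' @param max_proposals Cap on differential-evolution proposals (evaluated
#'   or skipped); `Inf` derives a generous cap from the budget.
#' @param force_eval_after Liveness guard for the gate: after this many
#'   consecutive skips the next proposal is evaluated regardless of its
#'   prediction, so wrongly rejected regions are re-sampled and the
#'   surrogate keeps receiving data even when it is pessimistic everywhere.
#' @param stagnation_window,stagnation_tol Stop the DE phase when the best
#'   cost improves by less than `stagnation_tol` (relative) over
#'   `stagnation_window` consecutive proposals.
#' @param refine_proposals True evaluations reserved for the refinement
#'   phase.
#' @param init_params Starting point of the random walk (default: the
#'   seeding values of [initial_params()]).
#' @param bounds A `parameter_bounds`.
#' @param mapper A [mapper_config()] for surrogate training.
#' @param seed Optional master seed for the whole run.
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(rw_steps = 1000L, step_scale = 0.02, F = 0.7,
                             CR = 0.9, elite_fraction = 0.25, capacity = 64L,
                             gate_threshold = Inf, retrain_every = 25L,
                             min_gate_r2 = 0.3,
                             variant = c("ecc", "general"),
                             max_proposals = Inf, force_eval_after = 3L,
                             stagnation_window = 500L,
                             stagnation_tol = 0.01, refine_proposals = 3L,
                             init_params = NULL, bounds = parameter_bounds(),
                             mapper = mapper_config(), seed = NULL) {
  variant <- match.arg(variant)
  structure(list(rw_steps = as.integer(rw_steps), step_scale = step_scale,
                 F = F, CR = CR, elite_fraction = elite_fraction,
                 capacity = as.integer(capacity),
                 gate_threshold = gate_threshold,
                 retrain_every = as.integer(retrain_every),
                 min_gate_r2 = min_gate_r2, variant = variant,
                 max_proposals = max_proposals,
                 force_eval_after = as.integer(force_eval_after),
                 stagnation_window = as.integer(stagnation_window),
                 stagnation_tol = stagnation_tol,
                 refine_proposals = as.integer(refine_proposals),
                 init_params = init_params, bounds = bounds, mapper = mapper,
                 seed = seed),
            class = "optimizer_config")
}

# Ledger accumulator: preallocated, grown by doubling.
ledger_new <- function(n0 = 1024L) {
  env <- new.env(parent = emptyenv())
  env$num <- matrix(NA_real_, n0, 15L)
  colnames(env$num) <- c("iter", paste0("p_", PARAM_NAMES),
                         paste0("n_", PARAM_NAMES), "predicted_cost",
                         "true_cost")
  env$phase <- character(n0)
  env$state <- character(n0)
  env$time <- character(n0)
  env$n <- 0L
  env
}

ledger_add <- function(env, phase, iter, raw, norm, predicted, cost, state) {
  if (env$n == nrow(env$num)) {
    env$num <- rbind(env$num, matrix(NA_real_, nrow(env$num), ncol(env$num)))
    env$phase <- c(env$phase, character(env$n))
    env$state <- c(env$state, character(env$n))
    env$time <- c(env$time, character(env$n))
  }
  env$n <- env$n + 1L
  env$num[env$n, ] <- c(iter, raw, norm, predicted, cost)
  env$phase[env$n] <- phase
  env$state[env$n] <- state
  env$time[env$n] <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
}

ledger_finish <- function(env) {
  i <- seq_len(env$n)
  out <- data.frame(phase = env$phase[i], env$num[i, , drop = FALSE],
                    state = env$state[i], timestamp = env$time[i],
                    row.names = NULL)
  out
}

#' Run the full three-phase parameter optimization
#'
#' Executes the random-walk seeding phase, the differential-evolution phase
#' with optional surrogate gating, and the surrogate-guided refinement
#' phase, against any evaluator honoring the evaluator contract: a function
#' `evaluator(params, state)` returning either a named list of property
#' results, or `list(results = ..., state = ...)` where `state` is an opaque
#' warm-start handle passed to the next call (the hook by which a molecular
#' dynamics evaluator reuses the previous configuration; the toy evaluator
#' ignores it). A failed evaluation is logged and the loop continues.
#'
#' @param evaluator The property evaluator (see Details).
#' @param reference A `reference_set` of targets.
#' @param weights A `cost_weights` object.
#' @param budget Total number of true evaluations allowed (all phases).
#' @param config An [optimizer_config()].
#' @return An object of class `water_optim_result`: best candidate, final
#'   population, surrogate, counters, best-cost history, and a ledger data
#'   frame with one row per proposed candidate (phase, raw and normalized
#'   parameters, predicted and true cost, state, timestamp).
#' @examples
#' land <- toy_landscape()
#' res <- run_optimization(toy_evaluator(land), budget = 120,
#'                         config = optimizer_config(rw_steps = 40, seed = 1))
#' res$best_cost
#' @export
run_optimization <- function(evaluator, reference = reference_set(),
                             weights = cost_weights(), budget,
                             config = optimizer_config()) {
  stopifnot(is.function(evaluator), is.numeric(budget), budget >= 0)
  if (!is.null(config$seed)) set.seed(config$seed)
  bounds <- config$bounds
  ledger <- ledger_new()
  pop <- new_population(config$capacity)
  counters <- c(n_evaluated = 0L, n_skipped = 0L, n_failed = 0L,
                n_proposals = 0L, n_retrains = 0L)
  best_cost <- Inf
  best_norm <- NULL
  best_history <- numeric(0)
  surrogate <- structure(list(trained = FALSE, config = config$mapper,
                              n_train = 0L), class = "water_mapper")
  eval_state <- NULL
  all_norm <- matrix(numeric(0), 0, 6)
  all_cost <- numeric(0)

  evaluate_true <- function(params, norm, phase, iter) {
    res <- tryCatch(evaluator(params, eval_state), error = function(e) e)
    if (inherits(res, "error")) {
      counters["n_failed"] <<- counters["n_failed"] + 1L
      ledger_add(ledger, phase, iter, params_as_vector(params), norm,
                 NA_real_, NA_real_, "failed")
      return(NA_real_)
    }
    if (!is.null(res$results)) {
      eval_state <<- res$state
      res <- res$results
    }
    cv <- model_cost(res, reference, weights, variant = config$variant)
    counters["n_evaluated"] <<- counters["n_evaluated"] + 1L
    upd <- accept_candidate(pop, norm, cv$cost)
    pop <<- upd$population
    all_norm <<- rbind(all_norm, as.numeric(norm))
    all_cost <<- c(all_cost, cv$cost)
    if (cv$cost < best_cost) {
      best_cost <<- cv$cost
      best_norm <<- as.numeric(norm)
    }
    best_history <<- c(best_history, best_cost)
    ledger_add(ledger, phase, iter, params_as_vector(params), norm,
               NA_real_, cv$cost, "evaluated")
    cv$cost
  }

  finish <- function() {
    structure(list(
      best_params = if (is.null(best_norm)) NULL
                    else denormalize_params(best_norm, bounds),
      best_norm = best_norm, best_cost = best_cost,
      population = pop, surrogate = surrogate,
      counters = counters, best_history = best_history,
      ledger = ledger_finish(ledger), config = config),
      class = "water_optim_result")
  }

  if (budget == 0) return(finish())

  # ---- Phase 1: random walk ----
  current <- if (is.null(config$init_params)) initial_params()
             else config$init_params
  check_bounds(current, bounds, action = "error")
  evaluate_true(current, normalize_params(current, bounds), "rw", 0L)
  step <- 1L
  while (step <= config$rw_steps && counters["n_evaluated"] < budget) {
    current <- random_walk_step(current, bounds, config$step_scale)
    evaluate_true(current, normalize_params(current, bounds), "rw", step)
    step <- step + 1L
  }
  # ensure DE has enough members even with a tiny rw_steps setting
  while (nrow(pop$norm) < 4L && counters["n_evaluated"] < budget) {
    current <- random_walk_step(current, bounds, config$step_scale)
    evaluate_true(current, normalize_params(current, bounds), "rw", step)
    step <- step + 1L
  }

  # ---- Phase 2: differential evolution with surrogate gate ----
  gate_on <- is.finite(config$gate_threshold)
  de_budget_end <- budget - min(config$refine_proposals, budget)
  max_props <- if (is.finite(config$max_proposals)) config$max_proposals
               else 20L * budget + 1000L
  evals_since_train <- 0L
  proposals_since_train <- 0L
  gate_trusted <- FALSE
  window_start_best <- best_cost
  window_count <- 0L
  consecutive_skips <- 0L
  iter <- 0L
  retrain <- function() {
    surrogate <<- train_mapper(all_norm, all_cost, config$mapper)
    counters["n_retrains"] <<- counters["n_retrains"] + 1L
    gate_trusted <<- isTRUE(surrogate$val_r2 >= config$min_gate_r2)
    evals_since_train <<- 0L
    proposals_since_train <<- 0L
  }
  while (counters["n_evaluated"] < de_budget_end &&
         counters["n_proposals"] < max_props &&
         nrow(pop$norm) >= 4L) {
    iter <- iter + 1L
    counters["n_proposals"] <- counters["n_proposals"] + 1L
    proposals_since_train <- proposals_since_train + 1L
    x <- de_propose(pop, config$F, config$CR, config$elite_fraction)
    params <- denormalize_params(x, bounds)
    # The gate screens while the population still contains members above the
    # threshold; once every retained point is inside the quality band,
    # proposals recombine known-good regions and screening has done its job
    # (a surrogate cannot resolve cost differences far below its fit error,
    # so keeping it active there only rejects good candidates). While
    # screening, a proposal predicted to improve on the worst retained
    # member is never skipped — such an evaluation advances the population
    # even when it is predicted above the quality threshold.
    worst_retained <- max(pop$cost)
    screening <- worst_retained > config$gate_threshold
    if (gate_on && screening && surrogate$trained && gate_trusted) {
      dec <- should_skip(surrogate, x, config$gate_threshold)
      if (dec$skipped && consecutive_skips < config$force_eval_after) {
        counters["n_skipped"] <- counters["n_skipped"] + 1L
        consecutive_skips <- consecutive_skips + 1L
        ledger_add(ledger, "de", iter, params_as_vector(params), x,
                   dec$predicted, NA_real_, "skipped")
        if (proposals_since_train >= 10L * config$retrain_every &&
            length(all_cost) >= config$mapper$min_rows)
          retrain()
        next
      }
      consecutive_skips <- 0L
    }
    cost_i <- evaluate_true(params, x, "de", iter)
    if (!is.na(cost_i)) evals_since_train <- evals_since_train + 1L
    if (gate_on && screening && evals_since_train >= config$retrain_every &&
        length(all_cost) >= config$mapper$min_rows)
      retrain()
    window_count <- window_count + 1L
    if (window_count >= config$stagnation_window) {
      rel_impr <- (window_start_best - best_cost) /
        max(window_start_best, .Machine$double.eps)
      if (rel_impr < config$stagnation_tol) break
      window_start_best <- best_cost
      window_count <- 0L
    }
  }

  # ---- Phase 3: surrogate-guided refinement ----
  n_ref <- min(config$refine_proposals, budget - counters[["n_evaluated"]])
  if (n_ref > 0 && nrow(pop$norm) >= 1L) {
    if (!surrogate$trained && length(all_cost) >= config$mapper$min_rows) {
      surrogate <- train_mapper(all_norm, all_cost, config$mapper)
      counters["n_retrains"] <- counters["n_retrains"] + 1L
    }
    if (surrogate$trained) {
      for (k in seq_len(n_ref)) {
        x <- refine(surrogate, pop)
        evaluate_true(denormalize_params(x, bounds), x, "refine", k)
        # retrain between refinement proposals so each one sees the latest data
        if (k < n_ref) {
          surrogate <- train_mapper(all_norm, all_cost, config$mapper)
          counters["n_retrains"] <- counters["n_retrains"] + 1L
        }
      }
    }
  }
  finish()
}

#' @export
print.water_optim_result <- function(x, ...) {
  cat("Water-model optimization result\n")
  cat(sprintf("  evaluated %d, skipped %d, failed %d (proposals %d, retrains %d)\n",
              x$counters["n_evaluated"], x$counters["n_skipped"],
              x$counters["n_failed"], x$counters["n_proposals"],
              x$counters["n_retrains"]))
  cat(sprintf("  best cost (%s): %.6g\n",
              if (x$config$variant == "ecc") "C_ECC" else "C_G", x$best_cost))
  if (!is.null(x$best_params)) print(x$best_params)
  invisible(x)
}

#' Write the candidate ledger to CSV
#'
#' One row per proposed candidate across all phases, with raw and normalized
#' parameters, predicted and true costs, evaluation state and timestamp.
#'
#' @param result A `water_optim_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ledger_csv <- function(result, path) {
  stopifnot(inherits(result, "water_optim_result"))
  write.csv(result$ledger, path, row.names = FALSE)
  invisible(path)
}
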
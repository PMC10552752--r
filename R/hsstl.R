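# HTLSS: hybrid teaching-learning / spring-search optimization ----------------
#
# Population metaheuristic for bounded continuous minimization, used here for
# wrapper feature selection and CNN hyperparameter tuning. It extends
# teaching-learning-based optimization (TLBO) with: opposition-based
# initialization, a five-teacher hierarchy with nearest-fitness grouping, an
# adaptive time-ratio teacher-knowledge blend, exploration-factor interaction
# moves, per-group elitism, and an optional Hooke-law spring pull toward the
# chief teacher. A degenerate configuration (one teacher, fixed teaching
# factor, no groups, `learner_rule = "tlbo"`, plain initialization) reduces
# exactly to canonical TLBO, which the test suite exploits as an independent
# oracle.
#
# Several published update rules in this family are ambiguous or internally
# inconsistent (undefined symbols, reused left-hand sides); where a rule had
# to be interpreted, the chosen reading is stated at the point of use and in
# the methods vignette.
#
# RNG draw order (all draws from one seeded stream), which determinism and
# oracle tests rely on:
#   init:            matrix(runif(pop * d), pop, d), column-major
#   teacher phase:   per moving member, in index order:
#                      [Tf draw if random] then d uniforms
#                      tlbo rule draws nothing else
#   learner phase:   per moving member, in index order:
#                      tlbo rule: 1 partner draw, then d uniforms
#                      hsstl rule: [Tf draw], d uniforms (teacher-knowledge
#                      blend), [ef draw], d uniforms (interaction move)

#' HTLSS configuration
#'
#' @param dim Problem dimensionality.
#' @param lo,up Bounds, scalars or length-`dim` vectors.
#' @param pop_size Population size (at least 6 for the full five-teacher
#'   hierarchy; smaller populations reduce the teacher count with a warning).
#' @param max_iters Iteration budget.
#' @param seed Integer seed for the optimizer's RNG stream.
#' @param n_teachers Teacher hierarchy size (chief first); default 5.
#' @param tf_policy Teaching factor: `"random"` draws `round(1 + U(0,1))`
#'   in \{1, 2\} per moving member, `"fixed1"`/`"fixed2"` pin it.
#' @param ef_policy Exploration factor for the interaction move: `"random"`
#'   (in \{1, 2\}, mirroring Tf) or `"off"` (disables the move).
#' @param grouping Assign learners to teachers by nearest fitness and apply
#'   per-group elitism; `FALSE` treats the population as one group under the
#'   chief.
#' @param elite_per_group Elites retained per group (currently 1).
#' @param stall_tol Stop early when the best fitness improves by less than
#'   this over `stall_window` iterations; 0 disables stalling.
#' @param stall_window Window for the stall check (default 20 iterations).
#' @param max_evals Optional objective-evaluation budget; the run stops once
#'   it is exhausted.
#' @param opposition Use opposition-based initialization (evaluate each
#'   random start and its bound reflection `lo + up - x`, keep the better).
#' @param learner_rule `"hsstl"` (teacher-knowledge blend + exploration
#'   interaction) or `"tlbo"` (canonical random-partner difference move).
#' @param spring_k Spring constant in `[0, 1]` for the optional Hooke-law
#'   pull of each learner toward the chief teacher; 0 (default) disables it.
#' @return An `hsstl_config` list.
#' @export
hsstl_config <- function(dim, lo = 0, up = 1, pop_size = 30L, max_iters = 100L,
                         seed = 1L, n_teachers = 5L,
                         tf_policy = c("random", "fixed1", "fixed2"),
                         ef_policy = c("random", "off"),
                         grouping = TRUE, elite_per_group = 1L,
                         stall_tol = 0, stall_window = 20L, max_evals = Inf,
                         opposition = TRUE,
                         learner_rule = c("hsstl", "tlbo"), spring_k = 0) {
  tf_policy <- match.arg(tf_policy)
  ef_policy <- match.arg(ef_policy)
  learner_rule <- match.arg(learner_rule)
  stopifnot(dim >= 1, pop_size >= 2, max_iters >= 1,
            spring_k >= 0, spring_k <= 1)
  lo <- rep_len(as.numeric(lo), dim)
  up <- rep_len(as.numeric(up), dim)
  if (any(up < lo)) stopf("hsstl_config(): need up >= lo in every dimension")
  structure(
    list(dim = as.integer(dim), lo = lo, up = up,
         pop_size = as.integer(pop_size), max_iters = as.integer(max_iters),
         seed = seed, n_teachers = as.integer(n_teachers),
         tf_policy = tf_policy, ef_policy = ef_policy,
         grouping = grouping, elite_per_group = as.integer(elite_per_group),
         stall_tol = stall_tol, stall_window = as.integer(stall_window),
         max_evals = max_evals, opposition = opposition,
         learner_rule = learner_rule, spring_k = spring_k),
    class = "hsstl_config"
  )
}

# Objective wrapper with an evaluation counter and finiteness check.
make_counting_objective <- function(objective) {
  count <- 0L
  f <- function(x) {
    count <<- count + 1L
    val <- objective(x)
    if (!is.numeric(val) || length(val) != 1L || is.na(val) || is.nan(val)) {
      stopf("objective returned a non-finite value at position (%s)",
            paste(signif(x, 4), collapse = ", "))
    }
    as.numeric(val)
  }
  list(f = f, count = function() count)
}

clamp <- function(x, lo, up) pmin(pmax(x, lo), up)

draw_factor <- function(policy) {
  switch(policy,
         random = round(1 + runif(1)),   # in {1, 2}
         fixed1 = 1,
         fixed2 = 2)
}

#' Opposition-based population initialization
#'
#' Samples `pop_size` uniform positions in the bounding box; for each, forms
#' the opposite point `lo + up - x` (the reflection about the box midpoint)
#' and keeps whichever of the pair has the better (lower) objective value.
#' With `opposition = FALSE` in the config the plain uniform sample is kept
#' and only evaluated.
#'
#' Note the classical reflection is used: the box midpoint is a fixed point,
#' and the opposite of a feasible point is always feasible.
#'
#' @param config An [hsstl_config()].
#' @param objective Function mapping a length-`dim` numeric vector to a
#'   single finite value (lower is better).
#' @return An `hsstl_pop`: list with `positions` (`pop_size x dim`),
#'   `fitness`, and bookkeeping fields.
#' @export
opposition_init <- function(config, objective) {
  d <- config$dim
  n <- config$pop_size
  u <- matrix(runif(n * d), n, d)
  pos <- sweep(sweep(u, 2, config$up - config$lo, "*"), 2, config$lo, "+")
  fit <- apply(pos, 1, objective)
  if (config$opposition) {
    opp <- sweep(-pos, 2, config$lo + config$up, "+")
    fit_opp <- apply(opp, 1, objective)
    better <- fit_opp < fit
    pos[better, ] <- opp[better, , drop = FALSE]
    fit[better] <- fit_opp[better]
  }
  structure(
    list(positions = pos, fitness = fit, teachers = integer(0),
         groups = integer(0), iteration = 0L),
    class = "hsstl_pop"
  )
}

#' Evaluate and cache a candidate's fitness
#'
#' Minimization convention: the fitness of a candidate is the raw objective
#' value, lower is better. Errors if the objective returns a non-finite
#' value, reporting the offending position.
#'
#' @param position Numeric position vector.
#' @param objective Objective function.
#' @return The objective value.
#' @export
fitness_eval <- function(position, objective) {
  if (any(!is.finite(position))) stopf("fitness_eval(): non-finite position")
  co <- make_counting_objective(objective)
  co$f(position)
}

#' Select the teacher hierarchy of a population
#'
#' Sorts members ascending by fitness (stable, so equal-fitness ties keep
#' their original index order) and designates the `n_teachers` best as
#' teachers, the best of all being the chief. Populations smaller than
#' `n_teachers + 1` reduce the teacher count with a warning so that at least
#' one learner remains.
#'
#' @param pop An `hsstl_pop`.
#' @param n_teachers Requested hierarchy size (default 5).
#' @return The population with `teachers` (member indices, chief first) set.
#' @export
select_teachers <- function(pop, n_teachers = 5L) {
  n <- nrow(pop$positions)
  k <- as.integer(n_teachers)
  if (n < k + 1L) {
    k <- max(1L, n - 1L)
    warning(sprintf("population of %d supports only %d teacher(s)", n, k),
            call. = FALSE)
  }
  ord <- order(pop$fitness)              # stable: ties by index
  pop$teachers <- ord[seq_len(k)]
  pop
}

#' Assign learners to teachers by nearest fitness
#'
#' Each non-teacher member is assigned to the teacher whose fitness value is
#' closest to its own (ties go to the better-ranked teacher). Teachers lead
#' their own groups.
#'
#' @param pop An `hsstl_pop` with teachers selected.
#' @return The population with `groups[i]` = index into `teachers` for every
#'   member (teachers map to their own group).
#' @export
assign_learners <- function(pop) {
  stopifnot(length(pop$teachers) >= 1)
  tfit <- pop$fitness[pop$teachers]
  groups <- vapply(seq_along(pop$fitness), function(i) {
    ti <- match(i, pop$teachers)
    if (!is.na(ti)) return(ti)
    which.min(abs(pop$fitness[i] - tfit))  # first (best teacher) wins ties
  }, integer(1))
  pop$groups <- groups
  pop
}

# Greedy move helper: evaluate candidate, accept if strictly better.
greedy_accept <- function(pop, i, cand, objective, budget_left) {
  if (!budget_left()) return(pop)
  f_new <- objective(cand)
  if (f_new < pop$fitness[i]) {
    pop$positions[i, ] <- cand
    pop$fitness[i] <- f_new
  }
  pop
}

#' Teacher phase of an HTLSS iteration
#'
#' Each moving member takes the mean-adjustment step: with per-dimension
#' uniforms `q` and teaching factor `Tf` in \{1, 2\},
#' `x_new = x_old + q * (x_teacher - Tf * M)`, clamped to the bounds and
#' accepted only on improvement. Under the `"hsstl"` rule the teacher is the
#' member's assigned group teacher and `M` the mean position of its group;
#' under the canonical `"tlbo"` rule every member moves toward the single
#' best member with `M` the whole-population mean.
#'
#' @param pop An `hsstl_pop` with teachers (and, for the grouped rule,
#'   learner assignments).
#' @param objective Objective function.
#' @param config An [hsstl_config()].
#' @param budget_left Internal evaluation-budget predicate.
#' @return The updated population.
#' @export
teacher_phase <- function(pop, objective, config,
                          budget_left = function() TRUE) {
  n <- nrow(pop$positions)
  tlbo <- config$learner_rule == "tlbo"
  movers <- if (tlbo) seq_len(n) else setdiff(seq_len(n), pop$teachers)
  for (i in movers) {
    if (!budget_left()) break
    tf <- draw_factor(config$tf_policy)
    q <- runif(config$dim)
    if (tlbo) {
      teacher_pos <- pop$positions[which.min(pop$fitness), ]
      m <- colMeans(pop$positions)
    } else {
      g <- pop$groups[i]
      teacher_pos <- pop$positions[pop$teachers[g], ]
      member_rows <- which(pop$groups == g)
      m <- colMeans(pop$positions[member_rows, , drop = FALSE])
    }
    cand <- clamp(pop$positions[i, ] + q * (teacher_pos - tf * m),
                  config$lo, config$up)
    pop <- greedy_accept(pop, i, cand, objective, budget_left)
  }
  pop
}

#' Learner phase of an HTLSS iteration
#'
#' Under the `"hsstl"` rule each learner makes up to three greedy,
#' bound-clamped moves:
#' \enumerate{
#'   \item Teacher-knowledge blend with the time ratio `t/T`:
#'     `x_new = x_old + r * ((1 - t/T) * x_old + (t/T) * x_teacher - x_old) * Tf`,
#'     which early in the run stays near the learner and late in the run
#'     pulls toward its teacher.
#'   \item Exploration interaction with factor `ef` in \{1, 2\}:
#'     `x_new = x_old + r * ((1 - t/T) * x_old + (t/T) * x_teacher - ef * x_old)`;
#'     with `ef = 2` the self-term turns repulsive, encouraging exploration.
#'   \item Optional spring pull `x_new = x_old + spring_k * (x_chief - x_old)`
#'     when `spring_k > 0`.
#' }
#' Afterwards each group's elite (snapshotted at phase entry) replaces the
#' group's worst member if better. Under the canonical `"tlbo"` rule the
#' phase is instead the classical random-partner difference move.
#'
#' @inheritParams teacher_phase
#' @param t,T_total Current iteration and iteration budget (the time ratio).
#' @return The updated population.
#' @export
learner_phase <- function(pop, objective, config, t = 1L,
                          T_total = config$max_iters,
                          budget_left = function() TRUE) {
  n <- nrow(pop$positions)
  if (config$learner_rule == "tlbo") {
    for (i in seq_len(n)) {
      if (!budget_left()) break
      j <- sample(setdiff(seq_len(n), i), 1L)
      r <- runif(config$dim)
      xi <- pop$positions[i, ]
      xj <- pop$positions[j, ]
      step <- if (pop$fitness[i] < pop$fitness[j]) xi - xj else xj - xi
      cand <- clamp(xi + r * step, config$lo, config$up)
      pop <- greedy_accept(pop, i, cand, objective, budget_left)
    }
    return(pop)
  }

  tr <- t / T_total
  elite <- lapply(seq_along(pop$teachers), function(g) {
    rows <- which(pop$groups == g)
    best <- rows[which.min(pop$fitness[rows])]
    list(position = pop$positions[best, ], fitness = pop$fitness[best])
  })
  chief <- pop$positions[pop$teachers[1L], ]
  learners <- setdiff(seq_len(n), pop$teachers)
  for (i in learners) {
    g <- pop$groups[i]
    teacher_pos <- pop$positions[pop$teachers[g], ]
    # (1) teacher-knowledge blend, scaled by the teaching factor
    if (!budget_left()) break
    tf <- draw_factor(config$tf_policy)
    r <- runif(config$dim)
    x <- pop$positions[i, ]
    cand <- clamp(x + r * ((1 - tr) * x + tr * teacher_pos - x) * tf,
                  config$lo, config$up)
    pop <- greedy_accept(pop, i, cand, objective, budget_left)
    # (2) exploration interaction
    if (config$ef_policy != "off") {
      if (!budget_left()) break
      ef <- draw_factor("random")
      r2 <- runif(config$dim)
      x <- pop$positions[i, ]
      cand <- clamp(x + r2 * ((1 - tr) * x + tr * teacher_pos - ef * x),
                    config$lo, config$up)
      pop <- greedy_accept(pop, i, cand, objective, budget_left)
    }
    # (3) optional Hooke-law spring pull toward the chief
    if (config$spring_k > 0) {
      if (!budget_left()) break
      x <- pop$positions[i, ]
      cand <- clamp(x + config$spring_k * (chief - x), config$lo, config$up)
      pop <- greedy_accept(pop, i, cand, objective, budget_left)
    }
  }
  # per-group elitism: the snapshotted elite replaces the group's worst
  for (g in seq_along(elite)) {
    rows <- which(pop$groups == g)
    worst <- rows[which.max(pop$fitness[rows])]
    if (elite[[g]]$fitness < pop$fitness[worst]) {
      pop$positions[worst, ] <- elite[[g]]$position
      pop$fitness[worst] <- elite[[g]]$fitness
    }
  }
  pop
}

#' Run the HTLSS optimizer
#'
#' Full loop: opposition-based initialization, then per iteration teacher
#' selection, nearest-fitness grouping, teacher phase and learner phase, with
#' per-group elitism and greedy acceptance throughout. Stops at the iteration
#' budget, when the evaluation budget is exhausted, or when the best fitness
#' has improved by less than `stall_tol` over the last `stall_window`
#' iterations.
#'
#' @param objective Function of a length-`dim` vector returning a finite
#'   scalar to minimize.
#' @param config An [hsstl_config()].
#' @return List with `best_position`, `best_fitness`, `history` (best-so-far
#'   fitness per executed iteration, non-increasing), `evals`, `iterations`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' cfg <- hsstl_config(dim = 5, lo = -5, up = 5, pop_size = 20,
#'                     max_iters = 40, seed = 3)
#' res <- run_hsstl(sphere, cfg)
#' res$best_fitness
#' @export
run_hsstl <- function(objective, config) {
  stopifnot(inherits(config, "hsstl_config"))
  co <- make_counting_objective(objective)
  budget_left <- function() co$count() < config$max_evals
  with_seed(config$seed, {
    pop <- opposition_init(config, co$f)
    best_idx <- which.min(pop$fitness)
    best <- list(position = pop$positions[best_idx, ],
                 fitness = pop$fitness[best_idx])
    history <- numeric(0)
    for (t in seq_len(config$max_iters)) {
      if (!budget_left()) break
      pop$iteration <- t
      pop <- select_teachers(pop, if (config$grouping) config$n_teachers else 1L)
      pop <- assign_learners(pop)
      pop <- teacher_phase(pop, co$f, config, budget_left)
      pop <- learner_phase(pop, co$f, config, t = t,
                           T_total = config$max_iters,
                           budget_left = budget_left)
      it_best <- which.min(pop$fitness)
      if (pop$fitness[it_best] < best$fitness) {
        best <- list(position = pop$positions[it_best, ],
                     fitness = pop$fitness[it_best])
      }
      history <- c(history, best$fitness)
      if (config$stall_tol > 0 && length(history) > config$stall_window) {
        w <- config$stall_window
        if (history[length(history) - w] - history[length(history)] <
            config$stall_tol) break
      }
    }
    list(best_position = best$position, best_fitness = best$fitness,
         history = history, evals = co$count(), iterations = length(history))
  })
}

#' Decode a continuous position into a feature mask
#'
#' Bit `j` is set iff `position[j] >= 0.5`. If no bit would be set, the
#' single largest coordinate is set instead, so a mask always selects at
#' least one feature.
#'
#' @param position Numeric vector in `[0, 1]^d`.
#' @return Logical vector of length `d`.
#' @export
decode_mask <- function(position) {
  stopifnot(length(position) >= 1)
  bits <- position >= 0.5
  if (!any(bits)) bits[which.max(position)] <- TRUE
  bits
}

# Nearest-centroid reference classifier used as the wrapper's inner model.
nearest_centroid_fit <- function(x, y) {
  classes <- sort(unique(y))
  centroids <- matrix(
    vapply(classes, function(c) colMeans(x[y == c, , drop = FALSE]),
           numeric(ncol(x))),
    nrow = length(classes), ncol = ncol(x), byrow = TRUE
  )
  list(classes = classes, centroids = centroids)
}

nearest_centroid_predict <- function(model, x) {
  d2 <- vapply(seq_len(nrow(model$centroids)), function(k) {
    rowSums(sweep(x, 2, model$centroids[k, ])^2)
  }, numeric(nrow(x)))
  model$classes[max.col(-d2, ties.method = "first")]
}

#' Wrapper feature selection by HTLSS
#'
#' Minimizes, over binary masks decoded from `[0, 1]^d` positions, the
#' misclassification rate of a nearest-centroid classifier on a seeded
#' stratified validation fold, plus a sparsity penalty
#' `alpha * (bits set) / d`. The fold is fixed for the whole search so every
#' candidate mask is scored on identical data.
#'
#' @param x Numeric feature matrix.
#' @param y Integer class labels (at least two classes).
#' @param config An [hsstl_config()] for the search space `[0, 1]^d`
#'   (`dim`, `lo`, `up` are overridden to match `x`). Defaults to a modest
#'   budget when omitted.
#' @param alpha Sparsity weight (default 0.01).
#' @param val_fraction Stratified validation fraction (default 0.3).
#' @return List with `mask` (logical), `features` (selected column names),
#'   `fitness`, `error` (validation error of the selected mask), and the
#'   full optimizer `result`.
#' @export
select_features <- function(x, y, config = NULL, alpha = 0.01,
                            val_fraction = 0.3) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stopf("select_features(): need at least 2 classes")
  d <- ncol(x)
  if (is.null(config)) {
    config <- hsstl_config(dim = d, pop_size = 20, max_iters = 30, seed = 1L)
  } else {
    config$dim <- d
    config$lo <- rep(0, d)
    config$up <- rep(1, d)
  }
  # fixed seeded stratified fold
  val_idx <- with_seed(config$seed + 1L, {
    unlist(lapply(split(seq_along(y), y), function(ids) {
      sample(ids)[seq_len(max(1L, floor(val_fraction * length(ids))))]
    }), use.names = FALSE)
  })
  tr_idx <- setdiff(seq_along(y), val_idx)
  mask_error <- function(bits) {
    xt <- x[tr_idx, bits, drop = FALSE]
    xv <- x[val_idx, bits, drop = FALSE]
    fit <- nearest_centroid_fit(xt, y[tr_idx])
    mean(nearest_centroid_predict(fit, xv) != y[val_idx])
  }
  objective <- function(pos) {
    bits <- decode_mask(pos)
    mask_error(bits) + alpha * sum(bits) / d
  }
  res <- run_hsstl(objective, config)
  mask <- decode_mask(res$best_position)
  list(mask = mask,
       features = (colnames(x) %||% paste0("f", seq_len(d)))[mask],
       fitness = res$best_fitness, error = mask_error(mask), result = res)
}
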
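test_that("opposition initialization reflects about the box midpoint and keeps the better", {
  cfg <- hsstl_config(dim = 1, lo = 0, up = 10, pop_size = 6, seed = 1)
  expect_equal(0 + 10 - 3, 7)              # reflection of 3 in [0, 10]
  expect_equal(0 + 10 - 5, 5)              # midpoint is a fixed point

  cfg <- hsstl_config(dim = 3, lo = -5, up = 5, pop_size = 20, seed = 11)
  set.seed(11)
  pop <- opposition_init(cfg, sphere)
  set.seed(11)
  u <- matrix(runif(20 * 3), 20, 3)
  raw <- u * 10 - 5
  opp <- -raw
  for (i in 1:20) {
    expect_lte(pop$fitness[i], min(sphere(raw[i, ]), sphere(opp[i, ])) + 1e-12)
  }
  expect_true(all(pop$positions >= -5 & pop$positions <= 5))
})

test_that("fitness evaluation is pure and rejects non-finite objectives", {
  expect_equal(fitness_eval(c(0, 0), sphere), 0)
  expect_equal(fitness_eval(c(1, 1), sphere), 2)
  expect_equal(fitness_eval(c(1, 1), sphere), fitness_eval(c(1, 1), sphere))
  expect_error(fitness_eval(c(1, 1), function(x) NaN), "non-finite")
})

test_that("teacher selection sorts ascending with stable ties; chief is the minimum", {
  pop <- structure(list(positions = matrix(0, 7, 1),
                        fitness = c(3, 1, 2, 5, 4, 9, 8),
                        teachers = integer(0), groups = integer(0),
                        iteration = 0L), class = "hsstl_pop")
  pop <- select_teachers(pop, 5)
  expect_equal(pop$fitness[pop$teachers], c(1, 2, 3, 4, 5))
  expect_equal(pop$teachers[1], 2L)

  tied <- pop
  tied$fitness <- rep(1, 7)
  tied <- select_teachers(tied, 5)
  expect_equal(tied$teachers, 1:5)          # first-index tie-break

  small <- pop
  small$positions <- matrix(0, 3, 1)
  small$fitness <- c(2, 1, 3)
  expect_warning(small <- select_teachers(small, 5), "supports only")
  expect_equal(length(small$teachers), 2L)
})

test_that("learners go to the teacher with nearest fitness", {
  pop <- structure(list(positions = matrix(0, 4, 1),
                        fitness = c(1, 2, 5, 4),   # teachers: 1, 2, 5; learner 4
                        teachers = c(1L, 2L, 3L), groups = integer(0),
                        iteration = 0L), class = "hsstl_pop")
  pop <- assign_learners(pop)
  expect_equal(pop$groups[4], 3L)           # |4 - 5| = 1 is minimal
  expect_equal(pop$groups[1:3], 1:3)        # teachers lead their own groups
})

test_that("teacher phase applies the mean-adjustment move and samples Tf in {1,2}", {
  # x_new = x_old + q * (teacher - Tf * M): teacher at Tf*M gives no move
  obj <- function(x) abs(x[1] - 100)        # any move toward 100 improves
  pop <- structure(list(positions = matrix(c(4, 2), 2, 1),
                        fitness = c(obj(4), obj(2)),
                        teachers = 1L, groups = c(1L, 1L), iteration = 0L),
                   class = "hsstl_pop")
  cfg <- hsstl_config(dim = 1, lo = 0, up = 10, pop_size = 2,
                      n_teachers = 1, tf_policy = "fixed1", seed = 1)
  # group mean M = (4 + 2)/2 = 3, teacher = 4 -> learner 2 moves by q * 1 > 0
  set.seed(5)
  out <- teacher_phase(pop, obj, cfg)
  set.seed(5)
  q <- runif(1)
  expect_equal(out$positions[2, 1], 2 + q * (4 - 1 * 3))

  # teacher exactly at Tf * M: displacement is zero
  pop2 <- pop
  pop2$positions <- matrix(c(3, 3), 2, 1)
  pop2$fitness <- c(obj(3), obj(3))
  out2 <- teacher_phase(pop2, obj, cfg)
  expect_equal(out2$positions, pop2$positions)

  tf <- replicate(1000, falldet:::draw_factor("random"))
  expect_true(all(tf %in% c(1, 2)))
  expect_true(all(c(1, 2) %in% tf))
})

test_that("learner phase keeps per-group elites and never worsens the group best", {
  set.seed(3)
  cfg <- hsstl_config(dim = 4, lo = -5, up = 5, pop_size = 12,
                      max_iters = 5, seed = 3)
  pop <- opposition_init(cfg, sphere)
  pop <- select_teachers(pop, cfg$n_teachers)
  pop <- assign_learners(pop)
  before <- vapply(seq_along(pop$teachers), function(g) {
    min(pop$fitness[pop$groups == g])
  }, numeric(1))
  pop2 <- learner_phase(pop, sphere, cfg, t = 1, T_total = 5)
  after <- vapply(seq_along(pop$teachers), function(g) {
    min(pop2$fitness[pop2$groups == g])
  }, numeric(1))
  expect_true(all(after <= before + 1e-12))
})

test_that("the full optimizer converges on the sphere with monotone history and feasible moves", {
  seen_infeasible <- FALSE
  obj <- function(x) {
    if (any(x < -5 - 1e-9) || any(x > 5 + 1e-9)) seen_infeasible <<- TRUE
    sphere(x)
  }
  cfg <- hsstl_config(dim = 5, lo = -5, up = 5, pop_size = 30,
                      max_iters = 100, seed = 3)
  res <- run_hsstl(obj, cfg)
  expect_lte(res$best_fitness, 1e-2)
  expect_true(all(diff(res$history) <= 0))
  expect_false(seen_infeasible)
  expect_equal(length(res$history), res$iterations)
})

test_that("the degenerate configuration reproduces canonical TLBO trajectories", {
  for (seed in c(2, 9)) {
    cfg <- hsstl_config(dim = 4, lo = -3, up = 3, pop_size = 10,
                        max_iters = 15, seed = seed, tf_policy = "fixed1",
                        ef_policy = "off", grouping = FALSE,
                        opposition = FALSE, learner_rule = "tlbo")
    res <- run_hsstl(sphere, cfg)
    oracle <- tlbo_oracle(sphere, dim = 4, lo = -3, up = 3, pop_size = 10,
                          max_iters = 15, seed = seed)
    expect_equal(res$history, oracle$history, tolerance = 1e-12)
    expect_equal(res$best_fitness, oracle$best_fitness, tolerance = 1e-12)
  }
})

test_that("HTLSS beats equal-budget random search on the 10-D sphere", {
  wins <- 0L
  for (seed in 1:20) {
    cfg <- hsstl_config(dim = 10, lo = -5, up = 5, pop_size = 30,
                        max_iters = 1000, max_evals = 3000, seed = seed)
    h <- run_hsstl(sphere, cfg)
    expect_lte(h$evals, 3000 + 1)
    rs_best <- local({
      set.seed(seed + 5000)
      min(apply(matrix(runif(3000 * 10, -5, 5), 3000, 10), 1, sphere))
    })
    if (h$best_fitness < rs_best) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("mask decoding thresholds at 0.5 with an argmax rescue", {
  expect_equal(decode_mask(c(0.9, 0.1, 0.5)), c(TRUE, FALSE, TRUE))
  expect_equal(decode_mask(c(0.1, 0.2)), c(FALSE, TRUE))
  expect_equal(decode_mask(rep(0.5, 4)), rep(TRUE, 4))
})

test_that("wrapper selection responds to the sparsity weight and redundancy", {
  gen <- gen_feature_matrix(c(60, 60, 60), n_informative = 1, n_noise = 3,
                            separation = 3, seed = 13)
  cfg <- hsstl_config(dim = 4, pop_size = 10, max_iters = 15, seed = 13)
  sel <- select_features(gen$x, gen$y, cfg, alpha = 1.0)
  expect_equal(sum(sel$mask), 1L)           # heavy penalty forces one feature
  expect_true(sel$mask[1])                  # ... and it is the informative one

  # at alpha = 0, masks differing only in a duplicated feature tie exactly:
  # doubling one squared-distance coordinate preserves the nearest centroid
  x2 <- cbind(gen$x, dup = gen$x[, 1])
  fit1 <- falldet:::nearest_centroid_fit(x2[, 1, drop = FALSE], gen$y)
  fit2 <- falldet:::nearest_centroid_fit(x2[, c(1, 5)], gen$y)
  expect_identical(
    falldet:::nearest_centroid_predict(fit1, x2[, 1, drop = FALSE]),
    falldet:::nearest_centroid_predict(fit2, x2[, c(1, 5)])
  )

  expect_error(select_features(gen$x, rep(0L, 180)), "2 classes")
})
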
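test_that("hs_params and sample_hs_params enforce the recommended grids", {
  expect_error(hs_params(hms = 1), "hms")
  expect_error(hs_params(hmcr = 1.2), "hmcr")
  expect_error(hs_params(mpap = 0), "mpap")
  p <- sample_hs_params(seed = 11)
  expect_true(any(abs(p$hmcr - seq(0.5, 0.7, 0.05)) < 1e-9))
  expect_true(any(abs(p$par - seq(0.6, 0.8, 0.05)) < 1e-9))
  expect_true(p$mpap %in% 10:18)
  expect_identical(p$hms, 1000L)
  expect_identical(p$max_iterations, 10000L)
  expect_identical(p$k, 200L)
  expect_error(sample_hs_params(overrides = list(hmcr = 0.95)), "grid")
  expect_error(sample_hs_params(overrides = list(mpap = 25)), "grid")
  fixed <- sample_hs_params(overrides = list(hmcr = 0.6, par = 0.7, mpap = 12,
                                             hms = 10, k = 5), seed = 1)
  expect_equal(fixed$hmcr, 0.6)
  expect_identical(fixed$k, 5L)
})

test_that("sampled hmcr values are uniform over the 5-point grid", {
  set.seed(303)
  n <- 10000
  draws <- replicate(n, sample_hs_params(overrides = list(hms = 2))$hmcr)
  freq <- table(factor(sprintf("%.2f", draws),
                       levels = sprintf("%.2f", seq(0.5, 0.7, 0.05))))
  # multinomial oracle: each cell 0.2 +/- 5 sd
  expect_true(all(abs(freq / n - 0.2) < 5 * sqrt(0.2 * 0.8 / n)))
})

test_that("pitch_adjust applies forced steps and clips with parity restored", {
  expect_identical(pitch_adjust(50, 14, 16, 1024, delta = 10), 60L)
  expect_identical(pitch_adjust(79, 14, 3, 81, odd = TRUE, delta = 10), 81L)
  expect_identical(pitch_adjust(17, 18, 16, 1024, delta = -18), 16L)
  # clip to an even bound on an odd axis steps inward
  expect_identical(pitch_adjust(79, 14, 3, 80, odd = TRUE, delta = 10), 79L)
  # literal mode adds exactly +mpap
  expect_identical(pitch_adjust(50, 10, 16, 1024, mode = "literal"), 60L)
})

test_that("random pitch steps stay admissible, signed and parity-preserving", {
  set.seed(55)
  vals <- replicate(2000, pitch_adjust(41, 14, 3, 81, odd = TRUE))
  expect_true(all(vals >= 3 & vals <= 81))
  expect_true(all(vals %% 2 == 1))
  expect_true(all(vals != 41))          # zero step excluded
  expect_true(any(vals < 41) && any(vals > 41))  # both signs occur
  expect_true(all(abs(vals - 41) <= 14))
})

test_that("initialize_hm fills to capacity sorted descending", {
  sp <- tiny_space()
  params <- hs_params(hms = 10, max_iterations = 10, k = 5, seed = 2)
  set.seed(2)
  # injective objective: distinct tuples get distinct scores
  obj <- function(hp) {
    v <- hscnn:::hp_as_integer(hp)
    (sum(v * c(1, 3, 7, 11, 17, 23)) %% 997) / 10
  }
  hm <- initialize_hm(sp, obj, params)
  expect_identical(hscnn:::hm_size(hm), 10L)
  expect_true(all(diff(hm$r) <= 0))
  # constant objective: any order valid, all r equal
  hm2 <- initialize_hm(sp, function(hp) 50, params)
  expect_true(all(hm2$r == 50))
  # 1-tuple space forces duplicates, which are permitted
  one <- hp_space(cld = 1, ks_min = 3, ks_max = 3, kc_min = 16, kc_max = 16,
                  dlnc_min = 256, dlnc_max = 256)
  hm3 <- initialize_hm(one, function(hp) 42, hs_params(hms = 2, seed = 1))
  expect_identical(hscnn:::hm_size(hm3), 2L)
  expect_identical(hscnn:::hp_as_integer(hm3$hp[[1]]),
                   hscnn:::hp_as_integer(hm3$hp[[2]]))
})

test_that("create_new_harmony branches follow HMCR and PAR", {
  sp <- tiny_space()
  set.seed(9)
  members <- replicate(5, random_hp(sp), simplify = FALSE)
  hm <- hscnn:::new_hm(members, r = seq(90, 50, length.out = 5))
  member_keys <- vapply(members, hscnn:::hp_key, character(1))

  # memory recall without pitch: output identical to a member
  p_recall <- hs_params(hms = 5, hmcr = 1, par = 0, mpap = 2)
  for (i in 1:50) {
    hp <- create_new_harmony(hm, sp, p_recall)
    expect_true(hscnn:::hp_key(hp) %in% member_keys)
  }

  # hmcr = 0 collapses to pure random draws (and all are valid)
  p_rand <- hs_params(hms = 5, hmcr = 0, par = 0.7, mpap = 2)
  for (i in 1:50) expect_valid_hp(sp, create_new_harmony(hm, sp, p_rand))

  # memory-recall frequency ~ hmcr (binomial oracle, 5 sd)
  n <- 10000
  p_mix <- hs_params(hms = 5, hmcr = 0.6, par = 0, mpap = 2)
  recalls <- vapply(seq_len(n), function(i)
    hscnn:::hp_key(create_new_harmony(hm, sp, p_mix)) %in% member_keys,
    logical(1))
  # non-members can collide with members by chance in a 64-tuple space, so
  # compare against the recall probability plus the collision background
  p_bg <- 5 / 64  # at most: random draw hits one of <=5 distinct members
  p_obs <- mean(recalls)
  expect_lt(abs(p_obs - 0.6) , 5 * sqrt(0.6 * 0.4 / n) + 0.4 * p_bg)
})

test_that("pitch-adjust frequency within recall branch follows PAR", {
  # wide space: adjusted vectors essentially never equal the recalled member
  sp <- hp_space(cld = 2, ks_min = 3, ks_max = 81, kc_min = 16, kc_max = 1024,
                 dlnc_min = 256, dlnc_max = 4096)
  set.seed(10)
  members <- replicate(3, random_hp(sp), simplify = FALSE)
  hm <- hscnn:::new_hm(members, r = c(90, 80, 70))
  member_keys <- vapply(members, hscnn:::hp_key, character(1))
  n <- 10000
  p <- hs_params(hms = 3, hmcr = 1, par = 0.7, mpap = 14)
  adjusted <- vapply(seq_len(n), function(i)
    !(hscnn:::hp_key(create_new_harmony(hm, sp, p)) %in% member_keys),
    logical(1))
  expect_lt(abs(mean(adjusted) - 0.7), 5 * sqrt(0.7 * 0.3 / n))
})

test_that("update_hm replaces the worst only on strict improvement", {
  sp <- tiny_space()
  set.seed(12)
  hps <- replicate(4, random_hp(sp), simplify = FALSE)
  hm <- hscnn:::new_hm(hps, r = c(96.7, 90, 85, 84.6))
  # strictly better candidate replaces the worst
  out <- update_hm(hm, harmony(random_hp(sp), 96.7))
  expect_true(out$updated)
  expect_gte(hscnn:::hm_worst_r(out$hm), 84.6)
  expect_identical(hscnn:::hm_size(out$hm), 4L)
  # tie with the minimum: memory byte-identical
  out2 <- update_hm(hm, harmony(random_hp(sp), 84.6))
  expect_false(out2$updated)
  expect_identical(out2$hm, hm)
})

test_that("update_hm equals a brute-force keep-best oracle on random streams", {
  sp <- tiny_space()
  for (seed in c(21, 22, 23)) {
    set.seed(seed)
    init_r <- round(runif(6, 0, 100), 1)
    hm <- hscnn:::new_hm(replicate(6, random_hp(sp), simplify = FALSE), init_r)
    cand_r <- round(runif(200, 0, 100), 1)
    for (r in cand_r) hm <- update_hm(hm, harmony(random_hp(sp), r))$hm
    expect_identical(hm$r, keep_best_oracle(init_r, cand_r, 6))
  }
})

test_that("run_hs finds the brute-force argmax on an enumerable space", {
  sp <- tiny_space()
  target <- hp_vector(ks = c(5, 3), kc = c(16, 17), dlnc = c(257, 256))
  sur <- surrogate_objective(target, sp)
  # exhaustive oracle
  all_hp <- enumerate_space(sp)
  scores <- vapply(all_hp, sur$fn, numeric(1))
  oracle_best <- all_hp[[which.max(scores)]]
  res <- run_hs(sur$fn, sp, hs_params(hms = 16, hmcr = 0.6, par = 0.7,
                                      mpap = 2, max_iterations = 500,
                                      k = 500, seed = 31))
  expect_identical(hscnn:::hp_as_integer(res$best$hp),
                   hscnn:::hp_as_integer(oracle_best))
  expect_equal(res$best$r, 100)
})

test_that("constant objective stops by stagnation exactly when the counter hits k", {
  sp <- tiny_space()
  res <- run_hs(function(hp) 50, sp,
                hs_params(hms = 4, hmcr = 0.5, par = 0.5, mpap = 2,
                          max_iterations = 1000, k = 10, seed = 5),
                cache = FALSE)
  expect_identical(res$termination, "stagnation")
  last <- nrow(res$trace)
  expect_identical(res$trace$delta_i[last], 10L)
  expect_true(all(res$trace$delta_i[-last] < 10L))
  # k = 1 stops after the first stagnant iteration
  res1 <- run_hs(function(hp) 50, sp,
                 hs_params(hms = 4, max_iterations = 1000, k = 1, seed = 6),
                 cache = FALSE)
  expect_identical(res1$termination, "stagnation")
})

test_that("best-so-far trace is non-decreasing and memory stays at capacity", {
  sp <- tiny_space()
  set.seed(41)
  noisy <- function(hp) runif(1, 0, 100)
  res <- run_hs(noisy, sp, hs_params(hms = 8, hmcr = 0.6, par = 0.7, mpap = 2,
                                     max_iterations = 300, k = 300, seed = 41),
                cache = FALSE)
  expect_true(all(diff(res$trace$best_r) >= 0))
  expect_identical(hscnn:::hm_size(res$hm), 8L)
  expect_true(all(diff(res$hm$r) <= 0))
  # trajectory rows exactly the best-update iterations
  expect_equal(res$trajectory$iteration,
               res$trace$iteration[res$trace$best_updated])
})

test_that("an injective objective with hms >= space size is solved at initialization", {
  sp <- hp_space(cld = 1, ks_min = 3, ks_max = 7, kc_min = 16, kc_max = 19,
                 dlnc_min = 256, dlnc_max = 258)  # 3*4*9 = 108 tuples
  all_hp <- enumerate_space(sp)
  obj <- function(hp) {
    v <- hscnn:::hp_as_integer(hp)
    (sum(v * c(5, 11, 3, 7)) %% 991) / 10
  }
  oracle <- max(vapply(all_hp, obj, numeric(1)))
  # initialization samples with replacement, so covering the space reliably
  # needs hms well above its size (miss probability ~ |S| exp(-hms/|S|))
  res <- run_hs(obj, sp, hs_params(hms = 1000, max_iterations = 1, k = 1,
                                   seed = 13))
  expect_equal(res$best$r, oracle)
  expect_false(any(res$trace$best_updated))  # nothing left to improve
})

test_that("identical seed and params give identical traces", {
  sp <- tiny_space()
  target <- hp_vector(ks = c(3, 3), kc = c(17, 17), dlnc = c(256, 257))
  sur <- surrogate_objective(target, sp)
  p <- hs_params(hms = 8, hmcr = 0.55, par = 0.65, mpap = 2,
                 max_iterations = 100, k = 50, seed = 77)
  r1 <- run_hs(sur$fn, sp, p)
  r2 <- run_hs(sur$fn, sp, p)
  expect_identical(r1$trace, r2$trace)
  expect_identical(hscnn:::hp_as_integer(r1$best$hp),
                   hscnn:::hp_as_integer(r2$best$hp))
})

test_that("max_evaluations caps distinct objective evaluations", {
  sp <- tiny_space()
  n_calls <- 0
  obj <- function(hp) { n_calls <<- n_calls + 1; runif(1, 0, 100) }
  res <- run_hs(obj, sp, hs_params(hms = 5, max_iterations = 1000, k = 1000,
                                   seed = 3),
                max_evaluations = 20)
  expect_identical(res$evaluations, 20L)
  expect_identical(res$termination, "budget")
})

test_that("random proposals under hmcr = 0 match random_hp distribution", {
  sp <- hp_space(cld = 1, ks_min = 3, ks_max = 5, kc_min = 16, kc_max = 16,
                 dlnc_min = 256, dlnc_max = 256)
  set.seed(88)
  hm <- hscnn:::new_hm(replicate(3, random_hp(sp), simplify = FALSE),
                       c(9, 5, 1))
  p0 <- hs_params(hms = 3, hmcr = 0, par = 1, mpap = 2)
  n <- 8000
  prop <- vapply(seq_len(n), function(i)
    create_new_harmony(hm, sp, p0)$ks, integer(1))
  direct <- vapply(seq_len(n), function(i) random_hp(sp)$ks, integer(1))
  # same two-point support with matching frequencies (5 sd binomial band)
  expect_setequal(unique(prop), unique(direct))
  expect_lt(abs(mean(prop == 3) - mean(direct == 3)),
            5 * sqrt(2 * 0.25 / n))
})
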
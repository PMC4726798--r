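test_that("feature similarity is symmetric, maximal on identity, graded by family", {
  cfg <- default_config()
  expect_equal(feature_similarity("X", "X", cfg), 1)
  expect_equal(feature_similarity("N", "N", cfg), 1)
  # high-load letters engage target-related processing; O's do not
  expect_lt(feature_similarity("O", "X", cfg), feature_similarity("N", "X", cfg))
  expect_equal(feature_similarity("K", "X", cfg), cfg$topdown$sim_high)
  expect_equal(feature_similarity("O", "N", cfg), cfg$topdown$sim_low)
  for (a in c("X", "O", "K", "P")) for (b in c("N", "Z", "S")) {
    expect_equal(feature_similarity(a, b, cfg), feature_similarity(b, a, cfg))
  }
  expect_error(feature_similarity("X", "Q", cfg), "unknown identity")
})

test_that("templates are periodic at the configured rate and span the trial", {
  cfg <- default_config()
  tpl <- target_template("X", 500, cfg)
  expect_equal(length(tpl), 500 / (1000 / cfg$topdown$r_template))
  expect_equal(unique(round(diff(tpl), 9)), 1000 / cfg$topdown$r_template)
  expect_true(all(tpl >= 0 & tpl < 500))
})

test_that("the temporal filter preserves spike counts exactly and gates on similarity", {
  cfg <- default_config()
  tpl <- target_template("X", 500, cfg)
  for (seed in 1:20) {
    r <- with_seed_test(seed, runif(1, 5, 80))
    pop <- generate_population(r, 10, 500, seed, cfg)
    below <- temporal_filter(pop, tpl, cfg$topdown$rho0 - 0.01, cfg)
    expect_identical(below$trains, pop$trains)   # bit-identical below gate
    above <- temporal_filter(pop, tpl, 1, cfg)
    expect_identical(lengths(above$trains), lengths(pop$trains))
    for (tr in above$trains) {
      expect_true(all(diff(tr) > 0))
      expect_true(all(tr >= 0 & tr < 500))
    }
  }
})

test_that("filtering a template-timed population is (near) a fixed point", {
  cfg <- default_config()
  tpl <- target_template("N", 500, cfg)
  pop <- structure(list(trains = list(as.numeric(tpl), as.numeric(tpl)),
                        r = cfg$topdown$r_template, M = 2, T = 500),
                   class = "spike_population")
  out <- temporal_filter(pop, tpl, 1, cfg)
  expect_equal(out$trains[[1]], as.numeric(tpl), tolerance = 1e-9)
})

test_that("the filter increases spike-template synchrony when applicable", {
  cfg <- default_config()
  tpl <- target_template("X", 500, cfg)
  sync <- function(trains, delta = cfg$topdown$delta) {
    mean(vapply(trains, function(tr) {
      if (!length(tr)) return(0)
      mean(vapply(tr, function(t) any(abs(tpl - t) <= delta / 2), logical(1)))
    }, numeric(1)))
  }
  for (seed in 1:10) {
    pop <- generate_population(40, 10, 500, seed, cfg)
    out <- temporal_filter(pop, tpl, 1, cfg)
    expect_gte(sync(out$trains), sync(pop$trains))
  }
})

test_that("cd_fire equals the brute-force triple scan on randomized instances", {
  cfg <- default_config()
  brute <- function(trains, t, delta) {
    hits <- vapply(trains, function(tr) {
      any(tr >= t - delta / 2 & tr <= t + delta / 2)
    }, logical(1))
    sum(hits) >= 2
  }
  n_checked <- 0
  for (seed in 1:120) {
    trains <- with_seed_test(seed, lapply(1:3, function(i) {
      sort(runif(rpois(1, 8), 0, 100))
    }))
    node <- structure(list(trains = trains, k = 2L), class = "cd_node")
    for (t in with_seed_test(seed + 1000, runif(9, 0, 100))) {
      for (delta in c(1, 3, 5)) {
        expect_identical(cd_fire(node, t, delta), brute(trains, t, delta))
        n_checked <- n_checked + 1
      }
    }
  }
  expect_gte(n_checked, 1000)
  expect_error(cd_fire(structure(list(trains = list(1, 2, 3), k = 2L),
                                 class = "cd_node"), -1, 3), "outside")
})

test_that("cd_fire needs at least two coincident inputs", {
  node <- structure(list(trains = list(c(50), numeric(0), numeric(0)),
                         k = 2L), class = "cd_node")
  expect_false(cd_fire(node, 50, delta = 3))         # 1 of 3
  node$trains[[2]] <- c(51)
  expect_true(cd_fire(node, 50.5, delta = 3))        # 2 of 3
  node$trains[[3]] <- c(49.5)
  expect_true(cd_fire(node, 50, delta = 3))          # 3 of 3
})

test_that("cd_node samples two distinct population neurons plus the template", {
  cfg <- default_config()
  pop <- generate_population(40, 10, 200, 3, cfg)
  tpl <- target_template("X", 200, cfg)
  node <- cd_node(pop$trains, tpl, c(2, 7))
  expect_length(node$trains, 3)
  expect_identical(node$trains[[3]], as.numeric(tpl))
  expect_error(cd_node(pop$trains, tpl, c(4, 4)))
})

test_that("control gain is 1 when silent, monotone in activity and gamma, capped", {
  cfg <- default_config()
  expect_equal(control_gain(0, 40, 25, config = cfg), 1)
  g1 <- control_gain(20, 40, 25, config = cfg)
  g2 <- control_gain(40, 40, 25, config = cfg)
  expect_gt(g1, 1); expect_gte(g2, g1)
  cfg2 <- deep_merge_test(cfg, list(topdown = list(gamma = cfg$topdown$gamma * 2)))
  expect_gte(control_gain(20, 40, 25, config = cfg2), g1)
  expect_equal(control_gain(1e6, 40, 25, config = cfg), cfg$topdown$g_max)
})

test_that("a template-synchronized population drives a larger gain than a jittered one", {
  # small gamma so both gains stay below the ceiling and are comparable
  cfg <- deep_merge_test(default_config(), list(topdown = list(gamma = 0.002)))
  tpl <- target_template("X", 500, cfg)
  pop <- generate_population(40, 20, 500, 5, cfg)
  aligned <- temporal_filter(pop, tpl, 1, cfg)
  gain_of <- function(p, seed) {
    d <- cfg$topdown$delta
    nodes <- with_seed_test(seed, lapply(1:40, function(i) {
      cd_node(p$trains, tpl, sample.int(p$M, 2))
    }))
    # exhaustive CD evaluation over the whole trial at 1 ms resolution
    fires <- sum(vapply(nodes, function(nd) {
      sum(vapply(seq(0.5, 499.5, by = 1), function(t) cd_fire(nd, t, d),
                 logical(1)))
    }, numeric(1)))
    control_gain(fires, 40, 500, config = cfg)
  }
  expect_gt(gain_of(aligned, 9), gain_of(pop, 9))
})

test_that("an incompatible distractor is amplified; a neutral one is not", {
  cfg <- default_config()
  cn_i <- basic_condition("low", "incompatible")
  cn_n <- basic_condition("low", "neutral")
  g_i <- g_n <- numeric(0)
  for (seed in 1:4) {
    d_i <- build_display(cn_i, "X", 0, 7, cfg)
    d_n <- build_display(cn_n, "X", 0, 7, cfg)
    o_i <- run_trial(d_i, cached_saliency(d_i, cfg), seed, cfg)
    o_n <- run_trial(d_n, cached_saliency(d_n, cfg), seed, cfg)
    di <- which(d_i$items$role == "distractor")
    g_i <- c(g_i, mean(o_i$gains[di, -1]))
    g_n <- c(g_n, mean(o_n$gains[di, -1]))
  }
  expect_gt(mean(g_i) - 1, 3 * (mean(g_n) - 1))
  expect_lt(mean(g_n), 1.25)
})
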
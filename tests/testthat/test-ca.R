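test_that("initialization places a reproducible compact disc", {
  p <- ca_params(lattice_size = 40)
  st <- init_state(p, 1)
  expect_equal(sum(st$state == 1), 1)
  expect_equal(which(st$state == 1), 40 * 19 + 20) # lattice center site
  st2 <- init_state(p, 100)
  expect_identical(init_state(p, 100)$state, st2$state)
  expect_equal(sum(st2$state == 1), 100)
  expect_true(all(st2$maturity[st2$state == 1] == p$m))
  expect_true(all(st2$dormancy == 0))
  # compactness: all cells within a tight radius of the center
  idx <- which(st2$state == 1, arr.ind = TRUE)
  expect_lt(max(sqrt((idx[, 1] - 20.5)^2 + (idx[, 2] - 20.5)^2)),
            sqrt(100 / pi) + 2)
  expect_error(init_state(ca_params(lattice_size = 10, capacity = 50), 51),
               "capacity")
})

test_that("a fully packed lattice produces no births", {
  p <- ca_params(lattice_size = 10, p_a = 0, p_d = 0.5, mu = 2)
  st <- init_state(p, 100)
  set.seed(1)
  st2 <- ca_step(st)
  expect_equal(attr(st2, "events")$births, 0)
  expect_equal(state_counts(st2)$n_viable, 100)
  expect_equal(state_counts(st2)$n_quiescent, 100)
})

test_that("degenerate step probabilities behave as limits", {
  p0 <- ca_params(p_d = 0, p_a = 0, mu = 0, lattice_size = 30)
  st <- init_state(p0, 50)
  set.seed(2)
  st2 <- ca_step(st)
  # state unchanged except counters
  expect_identical(st2$state, st$state)
  expect_true(all(st2$dormancy[st2$state == 1] == 1))
  expect_equal(st2$t, 1)

  p1 <- ca_params(p_d = 0, p_a = 1, mu = 0, lattice_size = 30)
  st <- init_state(p1, 50)
  set.seed(3)
  expect_equal(state_counts(ca_step(st))$n_viable, 0)
})

test_that("bookkeeping invariants hold along a stochastic run", {
  p <- ca_params(p_d = 0.3, p_a = 0.05, mu = 3, lattice_size = 60,
                 capacity = 900)
  set.seed(11)
  st <- init_state(p, 120)
  st <- apply_irradiation(st, 0.6, p_s = 0.5)
  for (i in 1:25) {
    st <- ca_step(st)
    ct <- state_counts(st)
    # grid tallies agree with the counts interface
    expect_equal(ct$n_total, sum(st$state > 0))
    expect_equal(ct$n_npma, sum(st$state == 2))
    # capacity respected
    expect_lte(ct$n_total, p$capacity)
    # maturity capped at m, counters non-negative
    expect_lte(max(st$maturity), p$m)
    expect_gte(min(st$dormancy), 0)
  }
})

test_that("fixed seeds give bit-identical simulations", {
  p <- ca_params(lattice_size = 80, global_pa = 0.055)
  run <- function() {
    set.seed(42)
    run_scenario(p, 300, 0.5, scenario = "global", t_max = 15,
                 detection_size = 50, stop_size = Inf)
  }
  a <- run(); b <- run()
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$final_state$state, b$final_state$state)
})

test_that("irradiation splits cells into survivors and NPMA binomially", {
  p <- ca_params(lattice_size = 120)
  st <- init_state(p, 10000)
  set.seed(5)
  st1 <- apply_irradiation(st, 1)
  expect_identical(st1$state, st$state) # surviving_fraction 1 is a no-op

  # S = 0.0255, p_s = 1: viable ~ Binomial(10000, S), remainder all NPMA
  st2 <- apply_irradiation(st, 0.0255, p_s = 1)
  nv <- sum(st2$state == 1)
  expect_lt(abs(nv - 255), 3 * sqrt(10000 * 0.0255 * 0.9745))
  expect_equal(sum(st2$state == 2), 10000 - nv)

  # S = 0.5, p_s = 0.5: NPMA ~ 2500 within 3 SE of the two-stage binomial
  st3 <- apply_irradiation(st, 0.5, p_s = 0.5)
  expect_lt(abs(sum(st3$state == 2) - 2500), 3 * sqrt(10000 * 0.25 * 0.75))
  expect_error(apply_irradiation(st, 0), "surviving_fraction")
})

test_that("the local inhibition mask is the Chebyshev ball around NPMA", {
  p <- ca_params(lattice_size = 21)
  st <- init_state(p, 0)
  expect_equal(sum(local_inhibition_mask(st, 2)), 0) # no NPMA, empty mask
  st$state[11, 11] <- 2L
  expect_equal(sum(local_inhibition_mask(st, 1)), 9) # 3x3 neighborhood
  expect_equal(sum(local_inhibition_mask(st, 2)), 25)
  # monotone in R on a mixed state
  set.seed(8)
  st$state[sample(21^2, 30)] <- 2L
  m1 <- local_inhibition_mask(st, 1)
  m2 <- local_inhibition_mask(st, 2)
  expect_true(all(m2[m1]))
})

test_that("low-density growth matches the mean-field factor", {
  # single (p_d, p_a) spot check; the full 6-combination grid runs in the
  # acceptance suite
  p <- ca_params(p_d = 0.3, p_a = 0.05, mu = 5, m = 0, lattice_size = 300)
  set.seed(13)
  gf <- replicate(8, {
    st <- init_state(p, 2000, placement = "scattered")
    for (i in 1:3) st <- ca_step(st)
    (state_counts(st)$n_viable / 2000)^(1 / 3)
  })
  expect_lt(abs(mean(gf) - mean_field_growth_factor(p)),
            3 * stats::sd(gf) / sqrt(length(gf)))
  expect_equal(mean_field_growth_factor(list(p_d = 0.2, p_a = 0.2)), 1)
})

test_that("dormancy fractions count cells that have not divided", {
  p <- ca_params(lattice_size = 20)
  st <- init_state(p, 40)
  expect_equal(dormancy_fraction(st, 1), 0) # fresh state: nobody dormant
  expect_equal(dormancy_fraction(st, 0), 1)
  # handcrafted registry: dormancy 5, 5, 1, 0 -> fraction(4) = 0.5
  st$state[] <- 0L
  st$dormancy[] <- 0L
  st$state[cbind(5:8, 5)] <- 1L
  st$dormancy[cbind(5:8, 5)] <- c(5L, 5L, 1L, 0L)
  expect_equal(dormancy_fraction(st, 4), 0.5)
  expect_equal(dormancy_fraction(st, 2), 0.5)
  expect_equal(dormancy_fraction(st, 6), 0)
  hist <- dormancy_histogram(st)
  expect_equal(hist$n_cells[hist$dormancy == 5], 2L)
})

test_that("extinction matches the branching-process fixed point", {
  # space non-limiting, maturity-saturated: offspring pgf gives q = p_a/p_d
  p <- ca_params(p_d = 0.3, p_a = 0.1, mu = 8, m = 0, lattice_size = 150)
  q_oracle <- p$p_a / p$p_d
  set.seed(17)
  ext <- replicate(300, {
    st <- init_state(p, 1, placement = "scattered")
    for (i in 1:40) {
      st <- ca_step(st)
      n <- sum(st$state == 1)
      if (n == 0 || n > 60) break
    }
    sum(st$state == 1) == 0
  })
  se <- sqrt(q_oracle * (1 - q_oracle) / 300)
  expect_lt(abs(mean(ext) - q_oracle), 3 * se)
})

test_that("extinction probability is certain without survivors and absent
          without death", {
  p_doom <- ca_params(p_d = 0, p_a = 1, lattice_size = 40)
  out <- local({
    set.seed(19)
    extinction_probability(p_doom, 50, 0.02, n_reps = 5, t_max = 5,
                           detection_size = 10, stop_size = Inf, p_s = 0)
  })
  expect_equal(out$extinction_probability, 1)
  p_safe <- ca_params(p_d = 0.3, p_a = 0, lattice_size = 60)
  out2 <- local({
    set.seed(20)
    extinction_probability(p_safe, 100, 0.5, n_reps = 5, t_max = 10,
                           detection_size = 10, stop_size = 500)
  })
  expect_equal(out2$extinction_probability, 0)
})

test_that("fitted growth rate decreases with the death probability", {
  rates <- vapply(c(0.01, 0.08, 0.15), function(pa) {
    p <- ca_params(p_d = 0.28, p_a = pa, lattice_size = 200)
    set.seed(23)
    r <- run_scenario(p, 500, 1, scenario = "none", t_max = 40,
                      detection_size = 500, stop_size = 4000)
    r$growth_fit$rate
  }, numeric(1))
  expect_true(all(diff(rates) < 0))
})

test_that("scenario preconditions are validated", {
  p <- ca_params(lattice_size = 40)
  expect_error(run_scenario(p, 10, 0.5, scenario = "global", t_max = 2),
               "global_pa")
  expect_error(run_scenario(p, 10, 0.5, scenario = "local", t_max = 2),
               "inhibition_radius")
  expect_equal(global_pa_preset(8), 0.055)
  expect_equal(global_pa_preset(12), 0.06)
  expect_equal(global_pa_preset(12, "alternative"), 0.07)
  expect_error(global_pa_preset(10), "presets")
})

test_that("sham irradiation leaves the baseline growth rate", {
  p <- ca_params(lattice_size = 200)
  set.seed(29)
  sham <- run_scenario(p, 500, 1, scenario = "none", t_max = 40,
                       detection_size = 500, stop_size = 4000)
  set.seed(29)
  base <- run_scenario(p, 500, 1, scenario = "none", t_max = 40,
                       detection_size = 500, stop_size = 4000)
  expect_identical(sham$trajectory, base$trajectory)
  expect_false(sham$extinct)
  expect_s3_class(glance(sham), "tbl_df")
  expect_s3_class(ggplot2::autoplot(sham), "ggplot")
})
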
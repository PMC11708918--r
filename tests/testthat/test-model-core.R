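test_that("mating table reproduces the printed cross-by-cross bookkeeping", {
  # pure heterozygote selfer: single nonzero row with weights ((1-k2)/4, 1/2, (1-k1)/4)
  tab <- mating_table(genotype_state(0, 1, 0), model_params(S = 1, k1 = 1, k2 = 1))
  nz <- dplyr::filter(tab, frequency > 0)
  expect_identical(nrow(nz), 1L)
  expect_identical(nz$mating, "self")
  expect_identical(nz$egg, "M1M2")
  expect_equal(nz$frequency, 1)
  expect_equal(unlist(nz[, c("M1M1", "M1M2", "M2M2")], use.names = FALSE),
               c(0, 1/2, 0))

  # fixed M1M1 population: only the SX and (1-S)X^2 rows survive
  tab <- mating_table(genotype_state(1, 0, 0), model_params(S = 0.4, k1 = 0.7, k2 = 0.7))
  nz <- dplyr::filter(tab, frequency > 0)
  expect_setequal(nz$frequency, c(0.4, 0.6))
  expect_true(all(nz$egg == "M1M1" & nz$sperm == "M1M1"))
  expect_true(all(nz$M1M1 == 1 & nz$M1M2 == 0 & nz$M2M2 == 0))

  # direct substitution: het x M2M2 outcross row frequency (1-S)YZ and
  # surviving M2M2 weight (1-k1)/2
  tab <- mating_table(genotype_state(0.25, 0.5, 0.25),
                      model_params(S = 0.6, k1 = 0.9, k2 = 0.5))
  row <- dplyr::filter(tab, egg == "M1M2", sperm == "M2M2", mating == "cross")
  expect_equal(row$frequency, 0.4 * 0.5 * 0.25)
  expect_equal(row$M2M2, (1 - 0.9) / 2)
  expect_equal(row$M1M2, 1 / 2)
  # heterozygote weights are never reduced by killing
  expect_true(all(tab$M1M2 %in% c(0, 0.25, 0.5, 1)))
})

test_that("mating frequencies partition into S (selfing) and 1-S (outcross)", {
  fx <- generate_fixtures(25, seed = 11)
  for (i in seq_len(nrow(fx))) {
    tab <- mating_table(genotype_state(fx$X[i], fx$Y[i], fx$Z[i]),
                        model_params(fx$S[i], fx$k1[i], fx$k2[i]))
    expect_equal(sum(tab$frequency[tab$mating == "self"]), fx$S[i])
    expect_equal(sum(tab$frequency[tab$mating == "cross"]), 1 - fx$S[i])
    expect_true(all(tab[, c("M1M1", "M1M2", "M2M2")] >= 0 &
                      tab[, c("M1M1", "M1M2", "M2M2")] <= 1))
  }
})

test_that("table summation gives the hand-enumerated next generations", {
  # all-heterozygote selfing with full penetrance: only heterozygotes survive
  res <- step_from_table(mating_table(genotype_state(0, 1, 0),
                                      model_params(1, 1, 1)))
  expect_equal(unname(res$state), c(0, 1, 0))
  expect_equal(res$mean_fitness, 1 / 2)

  # fixed population: no selection at all
  res <- step_from_table(mating_table(genotype_state(1, 0, 0),
                                      model_params(0.3, 1, 1)))
  expect_equal(unname(res$state), c(1, 0, 0))
  expect_equal(res$mean_fitness, 1)

  # full 9-row outcross enumeration at the symmetric point
  res <- step_from_table(mating_table(genotype_state(0.25, 0.5, 0.25),
                                      model_params(0, 1, 1)))
  expect_equal(allele_frequency(res$state), 0.5)
  expect_equal(res$state[["Y"]], 2 / 3)
  expect_equal(res$mean_fitness, 0.75)
})

test_that("compact recursion matches hand-derived values and the table oracle", {
  # complete selfing, single element: wbar = 1 - (Y/2) k1 (S/2)
  res <- step_monoecious(genotype_state(0.25, 0.5, 0.25),
                         model_params(S = 1, k1 = 1, k2 = 0))
  expect_equal(res$mean_fitness, 0.875)
  expect_equal(allele_frequency(res$state), 4 / 7)
  expect_equal(res$state[["Y"]], 2 / 7)

  # outcrossing with equal penetrances leaves allele frequency unchanged
  res <- step_monoecious(genotype_state(0.25, 0.5, 0.25),
                         model_params(S = 0, k1 = 0.7, k2 = 0.7))
  expect_equal(allele_frequency(res$state), 0.5)

  # no killing: neutral map with unit mean fitness
  res <- step_monoecious(genotype_state(0.1, 0.36, 0.54),
                         model_params(S = 0.4, k1 = 0, k2 = 0))
  expect_equal(allele_frequency(res$state), 0.28)
  expect_equal(res$mean_fitness, 1)
})

test_that("compact recursion equals the mating-table oracle on random states", {
  fx <- generate_fixtures(1000, seed = 1)
  gaps <- purrr::pmap_dbl(fx, mono_oracle_gap)
  expect_lt(max(gaps), 1e-12)
})

test_that("one-generation output always stays on the genotype simplex", {
  fx <- generate_fixtures(400, seed = 7)
  for (i in seq_len(nrow(fx))) {
    st <- step_monoecious(genotype_state(fx$X[i], fx$Y[i], fx$Z[i]),
                          model_params(fx$S[i], fx$k1[i], fx$k2[i]))$state
    expect_lt(abs(sum(st) - 1), 1e-12)
    expect_true(all(st >= 0))
  }
})

test_that("boundary and frozen-selfer equilibria are exact fixed points", {
  pars_grid <- generate_fixtures(50, seed = 21)
  for (i in seq_len(nrow(pars_grid))) {
    pars <- model_params(pars_grid$S[i], pars_grid$k1[i], pars_grid$k2[i])
    for (p_fixed in c(0, 1)) {
      res <- step_monoecious(state_from_pq(p_fixed, 0), pars)
      expect_equal(allele_frequency(res$state), p_fixed)
      expect_equal(res$state[["Y"]], 0)
    }
  }
  # S = 1, Y = 0: every allele frequency is an equilibrium
  for (p0 in seq(0.1, 0.9, 0.2)) {
    res <- step_monoecious(state_from_pq(p0, 0), model_params(1, 0.9, 0.5))
    expect_equal(allele_frequency(res$state), p0)
    expect_equal(res$state[["Y"]], 0)
  }
})

test_that("any outcrossing restores heterozygotes from a homozygote mixture", {
  for (S in c(0, 0.3, 0.9)) {
    for (p0 in c(0.1, 0.5, 0.8)) {
      res <- step_monoecious(state_from_pq(p0, 0), model_params(S, 0.8, 0.3))
      expect_equal(res$state[["Y"]],
                   (1 - S) * 2 * p0 * (1 - p0) / res$mean_fitness)
      expect_gt(res$state[["Y"]], 0)
    }
  }
})

test_that("random mating with equal penetrances never changes allele frequency", {
  fx <- generate_fixtures(200, seed = 5)
  for (i in seq_len(nrow(fx))) {
    pars <- model_params(0, fx$k1[i], fx$k1[i])
    st <- genotype_state(fx$X[i], fx$Y[i], fx$Z[i])
    expect_equal(allele_frequency(step_monoecious(st, pars)$state),
                 allele_frequency(st))
  }
})

test_that("single-element frequency change obeys the closed-form limits", {
  # complete selfing: delta-p = (p Y k / 4) / (1 - Y k / 4)
  for (k1 in c(0.2, 0.6, 1)) {
    for (Y in c(0.1, 0.4, 0.8)) {
      p <- 0.45
      st <- state_from_pq(p, Y)
      res <- step_monoecious(st, model_params(1, k1, 0))
      expect_equal(allele_frequency(res$state) - p,
                   (p * Y * k1 / 4) / (1 - Y * k1 / 4))
    }
  }
  # obligate outcrossing: delta-p = (p q Y k / 2) / (1 - q Y k / 2)
  for (k1 in c(0.2, 0.6, 1)) {
    for (Y in c(0.1, 0.4)) {
      p <- 0.3
      q <- 1 - p
      st <- state_from_pq(p, Y)
      res <- step_monoecious(st, model_params(0, k1, 0))
      expect_equal(allele_frequency(res$state) - p,
                   (p * q * Y * k1 / 2) / (1 - q * Y * k1 / 2))
    }
  }
})

test_that("sign of the frequency change follows the exposure-weighted sign law", {
  grid <- tidyr::expand_grid(p = seq(0.05, 0.95, 0.15), Y = c(0.05, 0.3),
                             S = c(0.2, 0.7), k1 = c(0.3, 0.9), k2 = c(0.5))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    Y <- min(g$Y, 2 * min(g$p, 1 - g$p))
    res <- step_monoecious(state_from_pq(g$p, Y), model_params(g$S, g$k1, g$k2))
    predicted <- sign(g$p * g$k1 * (g$S / 2 + (1 - g$p) * (1 - g$S)) -
                        (1 - g$p) * g$k2 * (g$S / 2 + g$p * (1 - g$S)))
    expect_equal(sign(allele_frequency(res$state) - g$p), predicted)
  }
})

test_that("trajectories are deterministic and reach the documented fates", {
  pars <- model_params(0, 0.9, 0.5)
  tj <- iterate_trajectory(state_from_pq(1, 0), pars, 100)
  expect_equal(tj$p, rep(1, 101))

  # low selfing: the stronger invader sweeps (fixation is approached only
  # algebraically under obligate outcrossing); high selfing: eliminated
  tj_fix <- iterate_trajectory(state_from_pq(0.2, 0), model_params(0, 0.9, 0.5), 2000)
  expect_gt(dplyr::last(tj_fix$p), 0.995)
  expect_true(all(diff(tj_fix$p) >= 0))
  tj_loss <- iterate_trajectory(state_from_pq(0.2, 0), model_params(0.6, 0.9, 0.5), 500)
  expect_lt(dplyr::last(tj_loss$p), 1e-6)

  # reproducibility and shape
  again <- iterate_trajectory(state_from_pq(0.2, 0), model_params(0.6, 0.9, 0.5), 500)
  expect_identical(tj_loss, again)
  expect_identical(nrow(tj_loss), 501L)
  expect_named(tj_loss, c("generation", "X", "Y", "Z", "p", "mean_fitness"))
})

test_that("allele frequency and state constructors enforce their domains", {
  expect_equal(allele_frequency(genotype_state(0.25, 0.5, 0.25)), 0.5)
  expect_equal(allele_frequency(genotype_state(1, 0, 0)), 1)
  expect_equal(allele_frequency(genotype_state(0.1, 0.36, 0.54)), 0.28)
  expect_error(genotype_state(0.5, 0.6, 0.2), class = "medeadyn_domain_error")
  expect_error(state_from_pq(0.1, 0.5), class = "medeadyn_domain_error")
  expect_error(model_params(1.2, 0.5, 0.5), class = "medeadyn_domain_error")
  expect_error(model_params(0.5, -0.1, 0.5), class = "medeadyn_domain_error")
})
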
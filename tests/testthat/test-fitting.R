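test_that("error_stats computes Err/MSE/MAE/MAE-per-molecule", {
  st <- error_stats(data.frame(deviation = c(1, -1), n_monomers = 9))
  expect_equal(st$err, 0)
  expect_equal(st$mse, 1)
  expect_equal(st$mae, 1)
  # constant deviations: err = d, mae = |d|, mse = d^2
  st2 <- error_stats(data.frame(deviation = rep(-2.5, 4), n_monomers = 15))
  expect_equal(st2$err, -2.5)
  expect_equal(st2$mae, 2.5)
  expect_equal(st2$mse, 6.25)
  expect_equal(st2$mae_per_mol, 2.5 / 15)
  expect_error(error_stats(data.frame(deviation = numeric(),
                                      n_monomers = integer())),
               class = "d4tune_domain_error")
  expect_error(error_stats(data.frame(deviation = c(1, 2),
                                      n_monomers = c(9, 15))),
               class = "d4tune_domain_error")
})

test_that("MAE per molecule reproduces the headline 9-mer worked example", {
  # a 9-mer ensemble with MAE 19.7 kcal/mol reads 2.19 kcal/mol per molecule
  st <- error_stats(data.frame(deviation = rep(19.7, 10), n_monomers = 9))
  expect_equal(st$mae_per_mol, 19.7 / 9)
  expect_equal(format_display(st$mae_per_mol), "2.19")
  expect_equal(st$err, st$mae)  # single-signed deviations: Err = MAE
})

test_that("display rounding is 2-decimal, half away from zero", {
  expect_equal(round_display(0.1911), 0.19)
  expect_equal(round_display(2.185), 2.19)
  expect_equal(round_display(-2.185), -2.19)
  expect_equal(round_display(0.005), 0.01)
  expect_equal(format_display(0.1911), "0.19")
})

test_that("optimize_s8 recovers exact constructions and flags flat objectives", {
  rec <- synthetic_fit_records(40, s6_true = 1, s8_true = 1.5, seed = 5)
  fit <- optimize_s8(rec, s6_fixed = 1)
  expect_equal(fit$scaling$s8, 1.5, tolerance = 1e-12)
  expect_equal(fit$objective_value, 0, tolerance = 1e-12)
  expect_false(fit$flat_flag)
  # optimum is no worse than any sampled curve point
  expect_true(all(fit$curve$mae >= fit$objective_value - 1e-12))

  flat <- rec; flat$e8_raw <- 0
  ff <- optimize_s8(flat, s6_fixed = 1, bounds = c(0.5, 5))
  expect_true(ff$flat_flag)
  expect_equal(ff$scaling$s8, 0.5)
})

test_that("breakpoint optimizer matches a dense grid oracle on random instances", {
  withr::with_seed(2024, {
    for (k in 1:100) {
      n <- sample(3:50, 1)
      rec <- data.frame(structure_id = as.character(seq_len(n)),
                        n_monomers = 9L,
                        deviation = stats::rnorm(n, 2, 3),
                        e6_raw = stats::runif(n, 0, 2),
                        e8_raw = stats::runif(n, 0, 2))
      fit <- optimize_s8(rec, s6_fixed = 1, bounds = c(0, 5))
      grid <- seq(0, 5, by = 1e-4)
      gmae <- scan_s8(rec, 1, grid)$mae
      expect_lte(fit$objective_value, min(gmae) + 1e-12)
    }
  })
})

test_that("joint and s6-only modes recover their constructions", {
  # joint on a noiseless (1.0, 2.0) construction
  rec <- synthetic_fit_records(60, 1.0, 2.0, seed = 8)
  fj <- optimize_s6_s8(rec, "joint")
  expect_equal(fj$scaling$s6, 1.0, tolerance = 1e-8)
  expect_equal(fj$scaling$s8, 2.0, tolerance = 1e-8)
  expect_equal(fj$objective_value, 0, tolerance = 1e-10)

  # the drastic-reduction mode pins S8 = 0 and rescales S6
  rec2 <- synthetic_fit_records(60, 0.4, 0.0, seed = 9)
  fz <- optimize_s6_s8(rec2, "s6_only_s8_zero")
  expect_equal(fz$scaling$s6, 0.4, tolerance = 1e-12)
  expect_equal(fz$scaling$s8, 0)
  expect_equal(fz$objective_value, 0, tolerance = 1e-12)
})

test_that("joint descent never increases the objective", {
  rec <- synthetic_fit_records(50, 0.8, 1.7, noise = 0.5, seed = 10)
  # trace the alternating descent by re-running with increasing iteration caps
  objs <- vapply(1:6, function(maxit)
    optimize_s6_s8(rec, "joint", max_iter = maxit)$objective_value, 0)
  expect_true(all(diff(objs) <= 1e-12))
})

test_that("scan_s8 agrees with direct per-structure recomputation and is convex", {
  fp <- water_fp()
  ds <- gen_dataset(ladder_specs(c(6, 9), 4, seed = 77),
                    mock_energy_spec(1, 2, noise_sigma = 0.4, seed = 6), fp)
  rec <- fit_records(assemble_deviations(ds$energies, "DFT", "MC"),
                     ds$components)
  grid <- seq(0, 5, length.out = 41)
  curve <- scan_s8(rec, 1, grid)
  # oracle: recompute each grid point by re-evaluating the full pair sum
  oracle <- vapply(grid, function(s8) {
    mean(vapply(seq_along(ds$structures), function(i) {
      s <- ds$structures[[i]]
      edis <- direct_dispersion_sum(s, fp, 1, s8)
      abs(rec$deviation[match(s$id, rec$structure_id)] - edis)
    }, 0))
  }, 0)
  expect_equal(curve$mae, oracle, tolerance = 1e-10)
  d2 <- diff(curve$mae, differences = 2)
  expect_true(all(d2 >= -1e-9))
  one <- scan_s8(rec, 1, grid = 2.0)
  expect_equal(nrow(one), 1)
})

test_that("optimal factors are invariant under a common positive rescaling", {
  rec <- synthetic_fit_records(40, 1.1, 1.9, noise = 0.3, seed = 12)
  f1 <- optimize_s6_s8(rec, "joint")
  rec2 <- rec
  rec2$deviation <- 7.3 * rec2$deviation
  rec2$e6_raw <- 7.3 * rec2$e6_raw
  rec2$e8_raw <- 7.3 * rec2$e8_raw
  f2 <- optimize_s6_s8(rec2, "joint")
  expect_equal(f2$scaling$s6, f1$scaling$s6, tolerance = 1e-10)
  expect_equal(f2$scaling$s8, f1$scaling$s8, tolerance = 1e-10)
})

test_that("statistics inequalities hold on random deviation sets", {
  withr::with_seed(31, {
    for (k in 1:25) {
      st <- error_stats(data.frame(
        deviation = stats::rnorm(sample(2:40, 1), sample(-3:3, 1), 2),
        n_monomers = sample(c(6, 9, 15, 27), 1)))
      expect_gte(st$mae, abs(st$err))
      expect_gte(st$mse, st$err^2)
      expect_lte(st$mae^2, st$mse + 1e-12)
      expect_equal(st$mae_per_mol, st$mae / st$n_monomers)
    }
  })
})

test_that("report tables render the 2-decimal display and full-precision JSON", {
  st <- list(B3LYP = list(
    `9` = error_stats(data.frame(deviation = rep(0.1911 * 9, 3),
                                 n_monomers = 9))))
  tab <- stats_table(st)
  out <- report_tables(tab)
  expect_match(out$tsv[2], "\t0.19$")
  parsed <- jsonlite::fromJSON(out$json)
  expect_equal(parsed$mae_per_mol, 0.1911, tolerance = 1e-12)

  empty <- report_tables(stats_table(list()))
  expect_length(empty$tsv, 1)  # header only, still a valid file
})
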
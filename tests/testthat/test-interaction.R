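test_that("one_body_sum is zero at the reference geometry and additive", {
  be <- harmonic_backend(k_r = 1000, k_theta = 100)
  s1 <- ref_monomer()
  expect_equal(one_body_sum(s1, partition_monomers(s1), be), 0)

  # one O-H stretched by +0.1 A: closed-form harmonic energy k_r/2 * 0.01
  th <- 104.348 * pi / 180
  stretched <- xyz_structure(c("O", "H", "H"),
                             rbind(c(0, 0, 0), c(0.95865 + 0.1, 0, 0),
                                   c(0.95865 * cos(th), 0.95865 * sin(th), 0)))
  e1 <- one_body_sum(stretched, partition_monomers(stretched), be)
  expect_equal(e1, 0.5 * 1000 * 0.1^2, tolerance = 1e-10)

  # two identical distorted monomers: exactly twice the single-monomer value
  both <- xyz_structure(rep(c("O", "H", "H"), 2),
                        rbind(stretched$xyz,
                              sweep(stretched$xyz, 2, c(50, 0, 0), `+`)))
  expect_equal(one_body_sum(both, partition_monomers(both), be), 2 * e1,
               tolerance = 1e-10)
})

test_that("interaction_deviation implements the one-body-subtracted bookkeeping", {
  rec <- list(structure_id = "x", n_monomers = 2L,
              e_total = c(DFT = -12, MC = -11),
              e_ref_monomer = c(DFT = -1, MC = -1),
              e_monomers = list())
  # method: -12 - 2*(-1) = -10; reference: -11 + 2 = -9; deviation -1
  d <- interaction_deviation(rec, "DFT", "MC")
  expect_equal(d$delta_total, -1)
  expect_equal(d$deviation, -1)
  d2 <- interaction_deviation(rec, "DFT", "MC",
                              onebody_method = 0.5, onebody_reference = 0.2)
  expect_equal(d2$delta_onebody, 0.3)
  expect_equal(d2$deviation, -1.3)
  # identical energies for both methods -> zero deviation
  same <- list(structure_id = "y", n_monomers = 3L,
               e_total = c(A = -5, B = -5), e_ref_monomer = c(A = 0, B = 0),
               e_monomers = list())
  expect_equal(interaction_deviation(same, "A", "B")$deviation, 0)
  expect_error(interaction_deviation(rec, "DFT", "CCSD"),
               class = "d4tune_data_error")
})

test_that("deviation identity and method antisymmetry hold", {
  fp <- water_fp()
  specs <- ladder_specs(c(6, 9), 3, seed = 21)
  ds <- gen_dataset(specs, mock_energy_spec(1, 2, noise_sigma = 0.3, seed = 4),
                    fp)
  dev <- assemble_deviations(ds$energies, "DFT", "MC")
  expect_equal(dev$deviation + dev$delta_onebody - dev$delta_total,
               rep(0, nrow(dev)))
  flipped <- assemble_deviations(ds$energies, "MC", "DFT")
  expect_equal(flipped$delta_total, -dev$delta_total)
  expect_equal(flipped$deviation, -dev$deviation)
})

test_that("size consistency: two far-apart copies double the deviation", {
  # additive mock energies: duplicating a cluster at a large separation
  # doubles every extensive quantity
  fp <- water_fp()
  spec <- cluster_spec(6, seed = 33)
  s <- gen_cluster(spec)
  far <- xyz_structure(rep(s$elements, 2),
                       rbind(s$xyz, sweep(s$xyz, 2, c(500, 0, 0), `+`)),
                       id = "double")
  mk_rec <- function(str) {
    part <- partition_monomers(str)
    base <- d4tune:::mock_base_energy(str, part)
    em <- monomer_energies(str, part, harmonic_backend())
    comp <- cluster_components(str, fp)
    disp <- dispersion_energy(comp, 1, 2)
    list(structure_id = str$id, n_monomers = length(part),
         e_total = c(DFT = base + sum(em), MC = base + sum(em) - disp),
         e_ref_monomer = c(DFT = 0, MC = 0),
         e_monomers = list(DFT = em, MC = em))
  }
  d1 <- interaction_deviation(mk_rec(s), "DFT", "MC")
  d2 <- interaction_deviation(mk_rec(far), "DFT", "MC")
  # dispersion across a 500 A gap is utterly negligible
  expect_equal(d2$delta_total, 2 * d1$delta_total, tolerance = 1e-6)
  expect_equal(d2$deviation, 2 * d1$deviation, tolerance = 1e-6)
})

test_that("apply_dispersion shifts deviations by the scaled components", {
  dev <- data.frame(structure_id = "a", n_monomers = 9L, delta_total = 10,
                    delta_onebody = 0, deviation = 10, stringsAsFactors = FALSE)
  comp <- data.frame(structure_id = "a", e6_raw = 2, e8_raw = 4,
                     stringsAsFactors = FALSE)
  expect_equal(apply_dispersion(dev, comp, 0, 0)$deviation, 10)
  shifted <- apply_dispersion(dev, comp, 1, 1)
  expect_equal(shifted$deviation, 4)
  expect_equal(shifted$n_monomers, 9L)
  # applying with s then -s recovers the original
  expect_equal(apply_dispersion(shifted, comp, -1, -1)$deviation, 10)
  bad <- data.frame(structure_id = "zzz", n_monomers = 9L, delta_total = 1,
                    delta_onebody = 0, deviation = 1, stringsAsFactors = FALSE)
  expect_error(apply_dispersion(bad, comp, 1, 1), class = "d4tune_data_error")
})

test_that("energy tables round-trip, convert hartree, and validate counts", {
  fp <- water_fp()
  ds <- gen_dataset(ladder_specs(c(6), 2, seed = 9),
                    mock_energy_spec(1, 2, noise_sigma = 0, seed = 2), fp)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_energy_table(ds$energies, f)
  back <- read_energy_table(f)
  expect_length(back, 2)
  expect_equal(back[[1]]$e_total[["MC"]], ds$energies[[1]]$e_total[["MC"]],
               tolerance = 1e-12)
  expect_equal(back[[2]]$e_monomers$DFT, ds$energies[[2]]$e_monomers$DFT,
               tolerance = 1e-12)

  # hartree units are converted by 627.509474
  writeLines(c("# units: hartree",
               "structure_id\tn_monomers\tDFT__total\tMC__total",
               "a\t2\t-1\t-1.1"), f)
  h <- read_energy_table(f)
  expect_equal(h[[1]]$e_total[["DFT"]], -627.509474)

  # per-monomer count mismatch
  writeLines(c("# units: kcal/mol",
               paste(c("structure_id", "n_monomers", "DFT__total",
                       paste0("DFT__monomer_", 1:8)), collapse = "\t"),
               paste(c("a", "9", "-5", rep("0.1", 8)), collapse = "\t")), f)
  expect_error(read_energy_table(f), class = "d4tune_format_error")
})

test_that("a geometric backend can supply one-body terms for both methods", {
  fp <- water_fp()
  ds <- gen_dataset(ladder_specs(c(6), 2, seed = 13),
                    mock_energy_spec(1, 2, noise_sigma = 0, seed = 3), fp)
  dev_tab <- assemble_deviations(ds$energies, "DFT", "MC", onebody = "table")
  dev_geo <- assemble_deviations(ds$energies, "DFT", "MC",
                                 onebody = harmonic_backend(),
                                 structures = ds$structures)
  # same backend on both sides cancels, as does the table route here
  expect_equal(dev_geo$deviation, dev_tab$deviation, tolerance = 1e-10)
})
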
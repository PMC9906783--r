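test_that("per-sublevel radiative rates scale as energy cubed and dipole squared", {
  base <- radiative_rate(0.08, c(0.1, 0, 0.05))
  expect_gt(base$rate_s, 0)
  expect_equal(base$lifetime_s, 1 / base$rate_s)
  # doubling every dipole component quadruples the rate
  expect_equal(radiative_rate(0.08, 2 * c(0.1, 0, 0.05))$rate_s,
               4 * base$rate_s, tolerance = 1e-12)
  # doubling the energy multiplies the rate by 8
  expect_equal(radiative_rate(0.16, c(0.1, 0, 0.05))$rate_s,
               8 * base$rate_s, tolerance = 1e-12)
  # rotation of the dipole vector leaves the rate unchanged
  th <- 0.7
  rot <- c(0.1 * cos(th) - 0.05 * sin(th), 0.1 * sin(th) + 0.05 * cos(th), 0)
  expect_equal(radiative_rate(0.08, c(0.1, 0.05, 0))$rate_s,
               radiative_rate(0.08, rot)$rate_s, tolerance = 1e-12)
  # zero dipole: non-emissive
  z <- radiative_rate(0.08, c(0, 0, 0))
  expect_equal(z$rate_s, 0)
  expect_identical(z$lifetime_s, Inf)
  expect_error(radiative_rate(-0.1, c(1, 0, 0)), "positive")
})

test_that("the Boltzmann-averaged lifetime has the correct limits", {
  m <- c(0.05, 0, 0)
  # degenerate sublevels with equal rates: tau = 1/k
  s_deg <- sublevel_set(rep(0.08, 3), rbind(m, m, m))
  k <- s_deg$rates_s[1]
  expect_equal(boltzmann_lifetime(s_deg), 1 / k, tolerance = 1e-12)
  # distinct gaps: T -> 0 populates only the lowest sublevel
  s <- sublevel_set(c(0.080, 0.0802, 0.0805),
                    rbind(c(0.02, 0, 0), c(0.06, 0, 0), c(0.09, 0, 0)))
  expect_equal(boltzmann_lifetime(s, temperature_K = 1e-6),
               1 / s$rates_s[1], tolerance = 1e-9)
  # T -> infinity: equal population, tau -> 3 / sum(k)
  expect_equal(boltzmann_lifetime(s, temperature_K = 1e12),
               3 / sum(s$rates_s), tolerance = 1e-6)
  # tau decreases when any single rate increases (fixed gaps and T)
  s_hi <- sublevel_set(c(0.080, 0.0802, 0.0805),
                       rbind(c(0.02, 0, 0), c(0.12, 0, 0), c(0.09, 0, 0)))
  expect_lt(boltzmann_lifetime(s_hi), boltzmann_lifetime(s))
  # bounded by the two temperature limits for ordered rates
  tau <- boltzmann_lifetime(s, 300)
  bounds <- sort(c(1 / s$rates_s[1], 3 / sum(s$rates_s)))
  expect_gte(tau, bounds[1] * (1 - 1e-12))
  expect_lte(tau, bounds[2] * (1 + 1e-12))
  # all-dark manifold flagged as non-emissive
  s0 <- sublevel_set(c(0.08, 0.081, 0.082), matrix(0, 3, 3))
  expect_identical(boltzmann_lifetime(s0), Inf)
})

test_that("Strickler-Berg correction divides by the squared refractive index", {
  expect_equal(strickler_berg_correct(10, n = 1), 10)
  expect_equal(strickler_berg_correct(10, n = 2), 2.5)
  expect_equal(strickler_berg_correct(10), 10 / 1.4793^2)
  expect_error(strickler_berg_correct(10, n = 0), "positive")
})

test_that("mean emission energy averages the three sublevels in eV", {
  m <- rbind(c(0.1, 0, 0), c(0.1, 0, 0), c(0.1, 0, 0))
  s <- sublevel_set(ev_to_hartree(c(2.2, 2.0, 2.1)), m)
  expect_equal(mean_emission_energy(s), 2.1, tolerance = 1e-9)
  # invariant to input ordering (sublevels sort by energy internally)
  s2 <- sublevel_set(ev_to_hartree(c(2.0, 2.1, 2.2)), m)
  expect_equal(mean_emission_energy(s2), mean_emission_energy(s))
  # unit round-trip is exact to floating precision
  expect_equal(hartree_to_ev(ev_to_hartree(2.345)), 2.345,
               tolerance = 1e-12)
})

test_that("sublevel tables parse, validate and post-process end to end", {
  path <- tempfile(fileext = ".tsv")
  rows <- c(
    "complex_id\tsublevel\tenergy\tunit\tmx\tmy\tmz",
    "cplx1\t1\t2.00\teV\t0.03\t0\t0",
    "cplx1\t2\t2.01\teV\t0.05\t0\t0",
    "cplx1\t3\t2.03\teV\t0.08\t0\t0")
  writeLines(rows, path)
  sets <- read_sublevel_table(path)
  expect_length(sets, 1)
  expect_equal(sets$cplx1$energies_hartree[1], 2.00 / 27.2114,
               tolerance = 1e-9)
  out <- lifetimes_from_table(path)
  expect_identical(nrow(out), 1L)
  expect_equal(out$em_mean_eV, mean(c(2.00, 2.01, 2.03)), tolerance = 1e-6)
  # solvent correction and Boltzmann average agree with the direct route
  tau_direct <- strickler_berg_correct(boltzmann_lifetime(sets$cplx1))
  expect_equal(out$lifetime_us, tau_direct * 1e6, tolerance = 1e-9)
  # hartree rows pass through unconverted
  writeLines(c(rows[1],
               "c2\t1\t0.074\thartree\t0.03\t0\t0",
               "c2\t2\t0.0741\thartree\t0.05\t0\t0",
               "c2\t3\t0.0743\thartree\t0.08\t0\t0"), path)
  expect_equal(read_sublevel_table(path)$c2$energies_hartree[1], 0.074)
  # malformed tables are refused
  writeLines(rows[1:3], path)
  expect_error(read_sublevel_table(path), "exactly 3")
  writeLines(c(rows[1:3], sub("eV", "kcal", rows[4])), path)
  expect_error(read_sublevel_table(path), "unit")
})
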
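test_that("allometric population rates match an independent evaluation", {
  # frozen values computed by hand/spreadsheet from the printed constants
  env <- environment_spec()
  expect_equal(carrying_capacity(env), 2171.767526707742, tolerance = 1e-12)
  expect_equal(growth_rate(env), 0.022072391578059278, tolerance = 1e-12)
  expect_equal(metabolic_rate(env), 0.023020315209327655, tolerance = 1e-12)
})

test_that("rate equations respond structurally as expected", {
  env <- environment_spec()
  env2 <- environment_spec(sigma_field = 6)
  expect_equal(metabolic_rate(env2), 2 * metabolic_rate(env))
  # switching off temperature, productivity and trophic corrections leaves
  # a pure power law in prey mass
  flat <- function(m) environment_spec(prey_mass_mg = m, E_K = 0,
                                       E_sigma = 0, z = 0, tl = 1)
  expect_equal(carrying_capacity(flat(1)),
               exp(-31.15) * (1 / 1000)^-0.72)
  expect_equal(carrying_capacity(flat(8)) / carrying_capacity(flat(1)),
               8^-0.72)
})

test_that("isoclines have their closed forms and limits", {
  pp <- population_params(N0 = 150, h = 1, fmax_per_h = 6.7)
  with(pp, expect_equal(predator_isocline(pp),
                        x * N0 / (e * omega * fmax - x)))
  # the pole: as x approaches the energetic ceiling, N* diverges
  near <- population_params(N0 = 150, h = 1.2, fmax_per_h = 6.7)
  near$x <- near$e * near$omega * near$fmax * 0.999999
  expect_gt(predator_isocline(near), 1e6 * predator_isocline(pp))
  # infeasibility is signalled, not an error
  bad <- population_params(N0 = 150, h = 1.2, fmax_per_h = 6.7)
  bad$x <- bad$e * bad$omega * bad$fmax * 1.01
  ns <- predator_isocline(bad)
  expect_true(is.na(ns))
  expect_true(attr(ns, "infeasible"))

  expect_equal(prey_isocline(pp, pp$K), 0)
  N <- seq(1, pp$K, length.out = 50)
  expect_true(all(prey_isocline(pp, N) >= 0))
  # h = 1, N0 -> 0 reduces to the classical Rosenzweig-MacArthur isocline
  pp0 <- population_params(N0 = 1e-12, h = 1, fmax_per_h = 6.7)
  expect_equal(prey_isocline(pp0, N),
               pp0$r * (pp0$K - N) * N / (pp0$K * pp0$omega * pp0$fmax),
               tolerance = 1e-9)
})

test_that("both growth equations vanish at the interior equilibrium", {
  set.seed(99)
  for (i in 1:100) {
    pp <- population_params(N0 = exp(runif(1, 2, 7)),
                            h = exp(runif(1, -0.2, 0.6)),
                            fmax_per_h = runif(1, 2, 12),
                            e = runif(1, 0.3, 1), omega = runif(1, 0.2, 1))
    N_star <- predator_isocline(pp)
    if (!is.finite(N_star) || N_star >= pp$K) next
    P_star <- prey_isocline(pp, N_star)
    feeding <- with(pp, fmax * N_star^h / (N0^h + N_star^h))
    dN <- with(pp, r * N_star * (1 - N_star / K) - omega * feeding * P_star)
    dP <- with(pp, e * omega * feeding * P_star - x * P_star)
    expect_lt(abs(dN), 1e-9)
    expect_lt(abs(dP), 1e-9)
  }
})

test_that("equilibria are classified against the patch boundary", {
  pp <- population_params(N0 = 181, h = 1.284, fmax_per_h = 6.7)
  tiny <- classify_equilibrium(pp, 0.04)
  expect_equal(tiny$status, "predator_extinct")
  expect_equal(tiny$N_star, pp$K)   # prey grows to capacity
  expect_equal(tiny$P_star, 0)
  expect_equal(tiny$extinction_boundary, 2 / 0.04)

  big <- classify_equilibrium(pp, 100)
  expect_equal(big$status, "coexistence")
  expect_equal(big$P_star, prey_isocline(pp, big$N_star))

  # status can only flip from extinct to coexistence as area grows
  areas <- c(0.04, 0.16, 1, 4, 16, 36, 64, 100)
  st <- vapply(areas, function(a) classify_equilibrium(pp, a)$status,
               character(1))
  coexist <- st == "coexistence"
  expect_true(all(diff(coexist) >= 0))

  # an energetically infeasible predator is extinct at any area
  bad <- population_params(N0 = 181, h = 1.284, fmax_per_h = 6.7)
  bad$x <- bad$e * bad$omega * bad$fmax * 1.5
  expect_equal(classify_equilibrium(bad, 100)$status, "predator_extinct")
})

test_that("the boundary contract is two individuals per patch", {
  pp <- population_params(N0 = 181, h = 1.284, fmax_per_h = 6.7)
  for (a in c(0.04, 1, 36)) {
    eq <- classify_equilibrium(pp, a)
    expect_equal(eq$extinction_boundary * a, 2)
  }
})

test_that("the coexistence map shows the refuge-rescue pattern", {
  fit <- fr_params(ln_c_n0 = 4.6, a_n0 = -0.01, b_n0 = 1.7, ln_c_h = 0.25,
                   ln_fmax = log(6.7))
  areas <- c(0.04, 0.16, 0.64, 1.44, 2.56, 4, 16, 36, 49, 64, 81, 100)
  refs <- seq(0.05, 0.75, by = 0.05)
  m <- coexistence_map(fit, areas, refs)
  expect_equal(nrow(m), length(areas) * length(refs))

  # smallest patch at the lowest refuge: predator extinct, prey at K
  c00 <- m[m$area_m2 == 0.04 & m$refuge_fraction == 0.05, ]
  expect_equal(c00$status, "predator_extinct")

  # survival frontier (smallest coexistence area) shrinks with refuge
  frontier <- sapply(refs, function(R) {
    ok <- m$refuge_fraction == R & m$status == "coexistence"
    if (any(ok)) min(m$area_m2[ok]) else Inf
  })
  expect_true(all(diff(frontier) <= 0))
  expect_lt(frontier[length(refs)], frontier[1])

  # within a coexisting patch size, both densities increase with refuge
  row <- m[m$area_m2 == 100 & m$status == "coexistence", ]
  row <- row[order(row$refuge_fraction), ]
  expect_true(all(diff(row$N_star) > 0))
  expect_true(all(diff(row$P_star) > 0))
})

test_that("numerical dynamics agree with the analytical equilibrium", {
  pp <- population_params(N0 = 300, h = 1.284, fmax_per_h = 6.7)
  N_star <- predator_isocline(pp)
  P_star <- prey_isocline(pp, N_star)
  tr <- simulate_dynamics(pp, N_star, P_star, t_end = 200)
  expect_lt(max(abs(tr$N - N_star)), 1e-6 * N_star)
  expect_lt(max(abs(tr$P - P_star)), 1e-6 * P_star)
  # without predators the prey converge to carrying capacity
  tr0 <- simulate_dynamics(pp, pp$K / 10, 0, t_end = 4000)
  expect_equal(tr0$N[nrow(tr0)], pp$K, tolerance = 1e-4)
  expect_equal(tr0$P[nrow(tr0)], 0)
})
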
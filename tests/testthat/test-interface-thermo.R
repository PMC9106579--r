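random_model <- function() {
  R <- runif(1, 1, 6); w <- runif(1, 20, 150)
  g_cg <- runif(1, 10, 25); g_tc <- runif(1, 10, 20)
  # keep x_eq inside the interface so the expansion is in its validity domain
  adsorption_model(R = R, w = w, gamma_tc = g_tc,
                   gamma_tg = g_tc + runif(1, -1, 1) * g_cg * R / w,
                   gamma_cg = g_cg, temperature = 300)
}

test_that("sharp-interface affinities match the Pickering limits", {
  # neutral wetting, Ax = 25 nm^2, gamma = 16.5 uJ/m2 at 300 K: ~0.1 k_BT
  m <- adsorption_model(R = 2, Ax = 25, w = 50, gamma_tg = 15, gamma_tc = 15,
                        gamma_cg = 16.5, temperature = 300)
  aff <- sharp_interface_affinities(m)
  expect_equal(aff$dG_g_neg, 0)
  expect_equal(aff$dG_s_neutral, 0.0996, tolerance = 1e-3)
  # at |delta gamma| = gamma_cg the particle detaches (affinity zero)
  m2 <- adsorption_model(R = 2, w = 50, gamma_tg = 31.5, gamma_tc = 15,
                         gamma_cg = 16.5, temperature = 300)
  expect_equal(sharp_interface_affinities(m2)$dG_s_sphere, 0)
})

test_that("the finite-interface energy has the stated boundary behaviour", {
  m <- adsorption_model(R = 2, w = 60, gamma_tg = 15, gamma_tc = 15,
                        gamma_cg = 16, temperature = 300)
  # cytosol-side boundary at neutral wetting: bulk value zero
  expect_equal(finite_interface_energy(m, m$w), 0)
  # centre of the interface at neutral wetting: -a0
  a0 <- equilibrium_and_affinity(m)$a0
  expect_equal(finite_interface_energy(m, 0), -a0, tolerance = 1e-12)
  expect_warning(finite_interface_energy(m, 2 * m$w), "clamped")
})

test_that("closed forms equal the numeric minimizer over random models", {
  set.seed(42)
  for (i in 1:100) {
    m <- random_model()
    eq <- equilibrium_and_affinity(m)
    if (!eq$expansion_valid) next
    opt <- optimize(function(x) finite_interface_energy(m, x),
                    c(-m$w + 1e-9, m$w - 1e-9), tol = 1e-13)
    # position agreement to 1e-6 of the interface width (x_eq can be ~0)
    expect_lt(abs(opt$minimum - eq$x_eq_nm), 1e-6 * m$w)
    expect_equal(-opt$objective, eq$dG_s_neg,
                 tolerance = 1e-6 * max(1e-6, abs(eq$dG_s_neg)))
  }
})

test_that("equilibrium relations reproduce worked examples", {
  # neutral wetting: x_eq = 0 and the surface affinity is a0
  m0 <- adsorption_model(R = 2, w = 60, gamma_tg = 15, gamma_tc = 15,
                         gamma_cg = 16)
  eq0 <- equilibrium_and_affinity(m0)
  expect_equal(eq0$x_eq_nm, 0)
  expect_equal(eq0$dG_s_neg, eq0$a0)
  # closed-form evaluation of the surface-affinity relation
  expect_equal(surface_affinity_relation(0.067, 0.1),
               0.067 + 0.05 + 0.01 / (32 * 0.067), tolerance = 1e-12)
  expect_equal(surface_affinity_relation(0.067, 0.1), 0.1217,
               tolerance = 1e-3)
  # sphere with R = w and delta gamma = gamma_cg: x_eq = w / 2
  m1 <- adsorption_model(R = 50, w = 50, gamma_tg = 31, gamma_tc = 15,
                         gamma_cg = 16)
  expect_equal(equilibrium_and_affinity(m1)$x_eq_nm, 25, tolerance = 1e-9)
  # a0 for a sphere equals pi R^2 gamma (R / w)
  msp <- adsorption_model(R = 3, w = 40, gamma_cg = 16, temperature = 300)
  a0_sphere <- granuleface:::area_energy_kBT(pi * 9 * 3 / 40, 16, 300)
  expect_equal(equilibrium_and_affinity(msp)$a0, a0_sphere,
               tolerance = 1e-12)
  # slope of the surface-affinity relation at zero bulk affinity is 1/2
  h <- 1e-6
  slope <- (surface_affinity_relation(0.067, h) -
              surface_affinity_relation(0.067, -h)) / (2 * h)
  expect_equal(slope, 0.5, tolerance = 1e-6)
})

test_that("interfacial-energy estimate inverts the neutral-wetting affinity", {
  expect_equal(estimate_gamma(0.1, 25, temperature = 300), 16.57,
               tolerance = 1e-2)
  expect_equal(estimate_gamma(0, 25), 0)
  expect_equal(estimate_gamma(0.1, 50, 300),
               estimate_gamma(0.1, 25, 300) / 2)
})

test_that("condensation pressure and adhesion follow their definitions", {
  out <- condensation_and_cavitation(n_L = 1e25, n = 1e22, n_sat = 1e22,
                                     E = 100)
  expect_equal(out$p_cond_Pa, 0)
  expect_false(out$unbounded_growth)
  out2 <- condensation_and_cavitation(1e25, exp(1) * 1e22, 1e22, E = 1e9,
                                      temperature = 300)
  expect_equal(out2$p_cond_Pa, 1e25 * granuleface:::kBT_joule(300),
               tolerance = 1e-9)
  out3 <- condensation_and_cavitation(1e25, exp(1) * 1e22, 1e22,
                                      E = out2$p_cond_Pa, temperature = 300)
  expect_true(out3$unbounded_growth) # p = E exceeds 5E/6
  ad <- adhesion_and_filament(16, 15, 15, per_subunit_kBT = 0.1,
                              nu_per_um = 500, L_um = 1)
  expect_equal(ad$W_uJ_m2, 16)
  expect_equal(ad$filament_energy_kBT, 50)
  expect_equal(adhesion_and_filament(16, 15, 15, 0.1, 500,
                                     0)$filament_energy_kBT, 0)
})

test_that("the robust fit recovers a0 and resists outliers", {
  # noise-free points generated from the relation are recovered exactly
  x <- seq(-0.1, 0.1, length.out = 50)
  y <- surface_affinity_relation(0.05, x)
  fit <- fit_a0(tibble::tibble(lnkg = x, lnks = y), seed = 1,
                n_realizations = 20)
  expect_equal(fit$a0, 0.05, tolerance = 1e-6)
  expect_lt(fit$a0_sd, 1e-6)
  # tidy/glance interfaces
  expect_equal(tidy(fit)$estimate, fit$a0)
  expect_equal(glance(fit)$nobs, 50)
  # one gross outlier barely moves the bisquare fit
  set.seed(33)
  xc <- rnorm(100, 0, 0.04)
  yc <- surface_affinity_relation(0.067, xc) + rnorm(100, 0, 0.01)
  clean <- fit_a0(tibble::tibble(lnkg = xc, lnks = yc), seed = 2,
                  n_realizations = 100)
  dirty_pts <- tibble::tibble(lnkg = c(xc, 0), lnks = c(yc, 1.0))
  dirty <- fit_a0(dirty_pts, seed = 2, n_realizations = 100)
  expect_lt(abs(dirty$a0 - clean$a0), 5 * clean$a0_sd)
})

test_that("the quadratic expansion reproduces the relation's coefficients", {
  m <- adsorption_model(R = 2.5, w = 80, gamma_tg = 15, gamma_tc = 15,
                        gamma_cg = 16, temperature = 300)
  a0 <- equilibrium_and_affinity(m)$a0
  expect_equal(a0, granuleface:::area_energy_kBT(0.75 * m$V0 / m$w, 16, 300))
  # numeric quadratic coefficient of -dG_s(-dG_g) equals 1/(32 a0)
  gs <- function(dgg) {
    mm <- m
    mm$delta_gamma <- -dgg / granuleface:::area_energy_kBT(m$A0, 1, 300)
    -optimize(function(x) finite_interface_energy(mm, x),
              c(-m$w + 1e-9, m$w - 1e-9), tol = 1e-13)$objective
  }
  h <- 0.01
  curv <- (gs(h) - 2 * gs(0) + gs(-h)) / h^2
  expect_equal(curv / 2, 1 / (32 * a0), tolerance = 1e-4)
})
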
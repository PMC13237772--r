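# Forward simulator: occupancy, site kinetics, titration tables, depletion.

test_that("occupancy follows the isotherm and its limits", {
  expect_equal(occupancy(4.8, 4.8), 0.5)
  expect_equal(occupancy(120, 4.8), 120 / 124.8, tolerance = 1e-12)
  expect_lt(occupancy(1e-9, 5), 1e-9)
  expect_gt(occupancy(1e6, 5), 0.999)
  expect_error(occupancy(1, -1), "kd > 0")
})

test_that("site uptake obeys the apo, saturation and no-effect identities", {
  for (regime in c("slow_mixture", "fast_exchange")) {
    # theta = 0: both regimes reduce to the apo exponential
    expect_equal(
      site_uptake(10, 50, 5000, 0, 5, regime = regime),
      0.894 * (1 - exp(-10 * 5 / 50)),
      tolerance = 1e-12
    )
    # t -> infinity: saturation at d_frac
    expect_equal(site_uptake(10, 50, 5000, 0.5, 1e6, regime = regime),
      0.894,
      tolerance = 1e-9
    )
    # p_bound == p_free: occupancy drops out
    expect_equal(
      site_uptake(10, 50, 50, 0.3, 5, regime = regime),
      site_uptake(10, 50, 50, 0.9, 5, regime = regime),
      tolerance = 1e-12
    )
    # uptake is non-decreasing in time
    ts <- c(0.005, 0.05, 0.5, 5, 50)
    up <- site_uptake(10, 50, 5000, 0.4, ts, regime = regime)
    expect_true(all(diff(up) > 0))
    expect_true(all(up >= 0 & up <= 0.894))
  }
  expect_error(site_uptake(10, 50, 5000, 1.2, 5), "theta")
})

test_that("simulated titrations are deterministic and schema-complete", {
  a <- fix_sim(noise = 0.05, seed = 13)
  b <- fix_sim(noise = 0.05, seed = 13)
  expect_identical(a$uptake, b$uptake) # bit-identical under a fixed seed
  c2 <- fix_sim(noise = 0.05, seed = 14)
  expect_false(identical(a$uptake$uptake_da, c2$uptake$uptake_da))
  # 5 peptides x (1 apo + 8 concentrations) x 3 replicates
  expect_identical(nrow(a$uptake), 5L * 9L * 3L)
  expect_true(all(c("state", "ligand_conc_uM", "n_exchangeable")
  %in% names(a$uptake)))
  # ground-truth sidecar covers every residue
  expect_identical(nrow(a$truth), fix_construct()$length)
  expect_error(
    simulate_titration(
      fix_construct(), data.frame(sequence = "GG", start = 60, end = 61),
      fix_sites(), sim_protocol()
    ),
    "construct|within"
  )
})

test_that("noiseless slow-mixture titrations return the true K_D through the
          full pipeline", {
  for (kd in c(2, 5, 20)) {
    sim <- fix_sim(kd = kd, noise = 0)
    fits <- fit_all_titrations(delta_uptake(sim$uptake))
    hit <- fits[fits$accepted, ]
    expect_gte(nrow(hit), 1)
    expect_lt(max(abs(hit$kd_uM - kd) / kd), 0.01)
  }
})

test_that("end-to-end recovery under replicate noise is unbiased enough", {
  # the standard design with sigma = 0.05 Da, 40 seeds
  errs <- vapply(1:40, function(s) {
    sim <- fix_sim(kd = 5, noise = 0.05, seed = s)
    fits <- fit_all_titrations(delta_uptake(sim$uptake))
    hit <- fits[fits$accepted & fits$target_id == "21-30", ]
    if (nrow(hit) == 0) {
      return(NA_real_)
    }
    (hit$kd_uM - 5) / 5
  }, numeric(1))
  errs <- errs[!is.na(errs)]
  expect_gt(length(errs), 30)
  expect_lt(median(abs(errs)), 0.10)
  # no gross systematic bias: mean error within 2 x MC standard errors
  expect_lt(abs(mean(errs)), 2 * sd(errs) / sqrt(length(errs)) + 0.02)
})

test_that("fast-exchange bias shrinks monotonically with shorter exposure", {
  kd <- 5
  bias <- vapply(c(0.05, 0.5, 5, 50), function(t) {
    apo <- site_uptake(5, 25, 2500, 0, t, regime = "fast_exchange")
    dd <- vapply(design_concs, function(L) {
      apo - site_uptake(5, 25, 2500, occupancy(L, kd), t,
        regime = "fast_exchange"
      )
    }, numeric(1))
    f <- fit_langmuir(
      data.frame(conc_uM = design_concs, delta_pct = 100 * dd / 0.894)
    )
    abs(f$kd_uM - kd) / kd
  }, numeric(1))
  expect_true(all(diff(bias) > 0)) # bias grows with exposure
  expect_lt(bias[1], 0.02) # near-linear regime at 3 s
})

test_that("ligand depletion solves the exact 1:1 quadratic", {
  # the lowest titration point of the standard design
  low <- ligand_depletion(1, 0.95, 4.8)
  expect_equal(low$free_ligand_uM, 0.8062, tolerance = 1e-4)
  expect_equal(low$depletion_fraction, 0.1514, tolerance = 1e-3)
  # vanishing protein: no depletion
  tiny <- ligand_depletion(1e-9, 0.95, 4.8)
  expect_lt(tiny$depletion_fraction, 1e-8)
  # bounds and mass-action consistency: free + bound = total
  set.seed(19)
  for (i in 1:20) {
    P0 <- runif(1, 0.1, 10)
    L0 <- runif(1, 0.1, 200)
    kd <- exp(runif(1, log(0.5), log(50)))
    r <- ligand_depletion(P0, L0, kd)
    expect_gt(r$free_ligand_uM, 0)
    expect_lt(r$free_ligand_uM, L0)
    bound <- L0 - r$free_ligand_uM
    pb <- P0 * r$free_ligand_uM / (kd + r$free_ligand_uM)
    expect_equal(bound, pb, tolerance = 1e-9)
  }
})

test_that("scramble operator conserves deuterium at every fraction", {
  site_d <- frag_site_d(seed = 23)
  lab <- labile_hydrogens(frag_seq)
  expect_identical(scramble_operator(site_d, 0, lab), site_d)
  full <- scramble_operator(site_d, 1, lab)
  expect_equal(full, sum(site_d) * lab / sum(lab), tolerance = 1e-12)
  for (f in seq(0, 1, by = 0.2)) {
    expect_equal(sum(scramble_operator(site_d, f, lab)), sum(site_d),
      tolerance = 1e-12
    )
  }
  expect_error(scramble_operator(site_d, 1.5, lab), "fraction")
})

test_that("simulated envelopes centroid to the population-weighted mean", {
  # slow-interconversion regime at intermediate occupancy: the envelope is
  # a bimodal mixture, but its centroid is still the occupancy-weighted
  # mean, which is what a centroid-based pipeline measures
  env <- natural_envelope(peptide_composition("GASTLIVEKR"), charge = 2)
  theta <- 0.4
  p_bound_site <- rep(0.1, 7)
  p_free_site <- rep(0.8, 7)
  bound_env <- incorporate_deuterium(env, p_bound_site)
  free_env <- incorporate_deuterium(env, p_free_site)
  # centroid of the theta-weighted population mixture
  mix <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(bound_env), intensity = theta * intensity),
    dplyr::mutate(tibble::as_tibble(free_env), intensity = (1 - theta) * intensity)
  )
  expected <- centroid(env) +
    (theta * sum(p_bound_site) + (1 - theta) * sum(p_free_site)) *
      1.006277 / 2
  expect_equal(centroid(mix), expected, tolerance = 1e-9)
})
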
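# Fragment-ladder algebra, residue-level titration, scrambling QC.

test_that("consecutive c ions resolve single residues by difference", {
  # d(c2) = 0.8, d(c3) = 1.2 -> residue 3 resolved at 0.4 Da
  ions <- tibble::tibble(
    ion_type = "c", ion_index = c(2, 3), charge = 1,
    centroid_mz_undeut = c(200, 300),
    centroid_mz_deut = c(200.8, 301.2)
  )
  lad <- fragment_ladder(ions, "GASTLIVEKR")
  res <- ladder_to_residues(lad)
  r3 <- res[res$kind == "resolved" & res$residue == 3, ]
  expect_equal(r3$d_da, 0.4, tolerance = 1e-9)
})

test_that("complete ladders conserve the precursor deuterium exactly", {
  site_d <- frag_site_d()
  lad <- simulate_ladder(frag_seq, site_d)
  res <- ladder_to_residues(lad)
  expect_equal(
    sum(res$d_da[res$kind %in% c("resolved", "segment")]),
    sum(site_d),
    tolerance = 1e-12
  )
  # prolines and the N-terminal pair are emitted as exclusions with zero D
  expect_setequal(res$residue[res$kind == "proline"], c(9, 13))
  expect_setequal(res$residue[res$kind == "excluded_nterm"], c(1, 2))
  expect_true(all(res$d_da[res$kind %in% c("proline", "excluded_nterm")] == 0))
})

test_that("c-only and z-only reconstructions agree residue-wise", {
  site_d <- frag_site_d(seed = 8)
  n <- nchar(frag_seq)
  ladc <- simulate_ladder(frag_seq, site_d,
    c_indices = 1:(n - 1), z_indices = integer(0)
  )
  ladz <- simulate_ladder(frag_seq, site_d,
    c_indices = integer(0), z_indices = 1:(n - 1)
  )
  rc <- dplyr::arrange(
    dplyr::filter(ladder_to_residues(ladc), kind == "resolved"), residue
  )
  rz <- dplyr::arrange(
    dplyr::filter(ladder_to_residues(ladz), kind == "resolved"), residue
  )
  expect_identical(rc$residue, rz$residue)
  expect_lt(max(abs(rc$d_da - rz$d_da)), 1e-9)
  # each reconstruction also conserves the total
  for (r in list(ladder_to_residues(ladc), ladder_to_residues(ladz))) {
    expect_equal(sum(r$d_da[r$kind %in% c("resolved", "segment")]),
      sum(site_d),
      tolerance = 1e-12
    )
  }
})

test_that("the partial c3-c7/c9-c11 + z9-z13 pattern resolves as forced", {
  # the measured ion set of the 16-mer worked example: c gap at c8 spans
  # positions 8-9, where position 9 is proline, so residue 8 is still
  # resolved; positions 12+ come from the c remainder
  site_d <- frag_site_d(seed = 12)
  lad <- simulate_ladder(frag_seq, site_d,
    c_indices = c(3:7, 9:11), z_indices = 9:13
  )
  res <- ladder_to_residues(lad)
  resolved <- sort(res$residue[res$kind == "resolved"])
  expect_true(all(c(4:8, 10, 11) %in% resolved))
  segs <- res[res$kind == "segment", ]
  # remainder beyond c11 spans the unresolved tail
  expect_true(any(segs$segment_start >= 12 & segs$segment_end == 16))
  # resolved values match the ground truth
  for (r in setdiff(resolved, c(1, 2))) {
    expect_equal(
      res$d_da[res$kind == "resolved" & res$residue == r],
      site_d[r],
      tolerance = 1e-9
    )
  }
})

test_that("c/z charge states and series merge by inverse variance", {
  ions <- tibble::tibble(
    ion_type = c("c", "c", "c", "c"),
    ion_index = c(2, 3, 2, 3), charge = c(1, 1, 2, 2),
    centroid_mz_undeut = c(200, 300, 100, 150),
    centroid_mz_deut = c(200.8, 301.2, 100.4, 150.6),
    sd = c(0.02, 0.02, 0.01, 0.01)
  )
  lad <- fragment_ladder(ions, "GASTLIVEKR")
  res <- ladder_to_residues(lad)
  r3 <- res[res$kind == "resolved" & res$residue == 3, ]
  expect_equal(r3$d_da, 0.4, tolerance = 1e-9)
  expect_lt(r3$sd_da, 0.02 * sqrt(2)) # tighter than either series alone
  # duplicate ion rows are rejected
  expect_error(
    fragment_ladder(dplyr::bind_rows(ions, ions[1, ]), "GASTLIVEKR"),
    "duplicate"
  )
})

test_that("residue-level titration recovers the planted K_D", {
  n <- nchar(frag_seq)
  obs <- setdiff(3:n, c(9, 13))
  p_free <- rep(20, n)
  p_bound <- p_free
  p_bound[8] <- p_free[8] * 50 # one binding residue
  kd_true <- 5
  mk <- function(L) {
    th <- if (L == 0) 0 else occupancy(L, kd_true)
    d <- numeric(n)
    d[obs] <- site_uptake(5, p_free[obs], p_bound[obs], th, 5,
      regime = "slow_mixture"
    )
    simulate_ladder(frag_seq, d,
      state = if (L == 0) "apo" else paste0("L_", L)
    )
  }
  res <- residue_titration(lapply(design_concs, mk), mk(0))
  hit <- res[res$kind == "resolved" & res$residue == 8, ]
  expect_true(hit$accepted)
  expect_lt(abs(hit$kd_uM - kd_true) / kd_true, 0.15)
  # non-binding residues fail with "no protection"
  others <- res[res$kind == "resolved" & res$residue != 8, ]
  expect_false(any(others$accepted))
  # apo == bound everywhere: every residue fails
  res0 <- residue_titration(lapply(design_concs, function(L) mk(0)), mk(0),
    conc_uM = design_concs
  )
  expect_false(any(res0$accepted))
})

test_that("median residue K_D error stays below 15% across seeded runs", {
  n <- nchar(frag_seq)
  obs <- setdiff(3:n, c(9, 13))
  errs <- vapply(1:25, function(s) {
    set.seed(s)
    kd_true <- exp(runif(1, log(1), log(20)))
    p_free <- rep(20, n)
    p_bound <- p_free
    p_bound[8] <- p_free[8] * 50
    mk <- function(L) {
      th <- if (L == 0) 0 else occupancy(L, kd_true)
      d <- numeric(n)
      d[obs] <- site_uptake(5, p_free[obs], p_bound[obs], th, 5,
        regime = "slow_mixture"
      ) + rnorm(length(obs), 0, 0.01)
      d[obs] <- pmin(pmax(d[obs], 0), 0.894)
      simulate_ladder(frag_seq, d,
        state = if (L == 0) "apo" else paste0("L_", L)
      )
    }
    res <- residue_titration(lapply(design_concs, mk), mk(0))
    hit <- res[res$kind == "resolved" & res$residue == 8, ]
    abs(hit$kd_uM - kd_true) / kd_true
  }, numeric(1))
  expect_lt(median(errs), 0.15)
})

test_that("P1-style scrambling metric is affine in the scramble fraction", {
  site_d <- frag_site_d(seed = 3)
  lab <- labile_hydrogens(frag_seq)
  n <- nchar(frag_seq)
  pct <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(f) {
    sc <- scramble_operator(site_d, f, lab)
    expect_equal(sum(sc), sum(site_d), tolerance = 1e-12) # conservation
    lad <- simulate_ladder(frag_seq, sc,
      c_indices = 2:(n - 2), z_indices = 2:(n - 2)
    )
    scrambling_p1(lad, site_d, precursor_d = sum(site_d))$scrambling_pct
  }, numeric(1))
  expect_equal(pct, c(0, 25, 50, 75, 100), tolerance = 1e-6)
  expect_equal(diff(pct), rep(25, 4), tolerance = 1e-6) # affine
  # flagging threshold
  sc <- scramble_operator(site_d, 0.5, lab)
  lad <- simulate_ladder(frag_seq, sc, c_indices = 2:14, z_indices = 2:14)
  rep50 <- scrambling_p1(lad, site_d, precursor_d = sum(site_d))
  expect_true(rep50$flagged)
  expect_equal(rep50$scrambling_pct, 50, tolerance = 2)
})

test_that("ammonia-loss check flags deuterium loss beyond threshold", {
  ok <- ammonia_loss_check(3.50, 3.48, 0.02)
  expect_equal(ok$d_difference_da, 0.02, tolerance = 1e-12)
  expect_false(ok$flagged)
  bad <- ammonia_loss_check(3.50, 3.10, 0.02)
  expect_equal(bad$d_difference_da, 0.4, tolerance = 1e-12)
  expect_true(bad$flagged)
  expect_error(ammonia_loss_check(-1, 0.5, 0.1), "non-negative")
  # the simulated difference grows with the scramble fraction
  site_d <- frag_site_d(seed = 5)
  lab <- labile_hydrogens(frag_seq)
  # model the ammonia-loss reporter as the N-terminal-most labile site: a
  # scrambled population moves deuterium onto it in proportion to fraction
  d_nh3 <- vapply(c(0, 0.25, 0.5, 1), function(f) {
    sum(scramble_operator(site_d, f, lab)[1:2])
  }, numeric(1))
  expect_true(all(diff(d_nh3) > 0))
})

test_that("fragment tables round-trip and compute d_content on read", {
  site_d <- frag_site_d()
  lad <- simulate_ladder(frag_seq, site_d, c_indices = 2:6, z_indices = 3:5)
  tab <- dplyr::mutate(lad$ions,
    sequence = frag_seq, start = 18, end = 33,
    state = "apo", exposure_min = 5, replicate = 1
  )
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tab, path)
  back <- read_fragment_table(path)
  expect_equal(back$d_content, lad$ions$d_content, tolerance = 1e-9)
})
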
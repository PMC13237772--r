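# Langmuir isotherm fitting, acceptance rules, and global aggregation.

test_that("noiseless series are recovered to machine-level accuracy", {
  set.seed(31)
  for (i in 1:10) {
    kd <- exp(runif(1, log(0.5), log(50)))
    dmax <- runif(1, 20, 60)
    s <- data.frame(conc_uM = design_concs)
    s$delta_pct <- langmuir(s$conc_uM, kd, dmax)
    f <- fit_langmuir(s)
    expect_true(f$converged)
    expect_lt(abs(f$kd_uM - kd) / kd, 1e-6)
    expect_lt(abs(f$dmax_pct - dmax) / dmax, 1e-6)
    # half-saturation identity
    expect_equal(langmuir(f$kd_uM, f$kd_uM, f$dmax_pct), f$dmax_pct / 2)
  }
})

test_that("the fitted curve is increasing in L and bounded by Dmax", {
  s <- data.frame(conc_uM = design_concs)
  s$delta_pct <- langmuir(s$conc_uM, 5, 30) + c(1, -1, 0.5, -0.5, 0, 1, -1, 0)
  f <- fit_langmuir(s)
  grid <- langmuir(seq(0.01, 500, length.out = 200), f$kd_uM, f$dmax_pct)
  expect_true(all(diff(grid) > 0))
  expect_true(all(grid < f$dmax_pct))
})

test_that("noisy fits agree with a 2-D grid-search oracle", {
  set.seed(32)
  for (i in 1:6) {
    kd <- exp(runif(1, log(1), log(30)))
    dmax <- runif(1, 25, 55)
    y <- langmuir(design_concs, kd, dmax) + rnorm(8, 0, 1)
    f <- fit_langmuir(data.frame(conc_uM = design_concs, delta_pct = y))
    g <- oracle_grid_fit(design_concs, y)
    # within one grid cell of the brute-force optimum
    expect_lt(abs(log(f$kd_uM) - log(g$kd)), log(g$kd_step) * 1.5 + 1e-9)
    expect_lt(abs(f$dmax_pct - g$dmax), g$dmax_step * 1.5 + 1e-9)
  }
})

test_that("degenerate series produce flagged failures, not silent drops", {
  s <- data.frame(conc_uM = design_concs, delta_pct = rep(-1, 8))
  f <- fit_langmuir(s)
  expect_false(f$converged)
  expect_match(f$reason, "no protection")
  expect_false(f$accepted)
  expect_error(
    fit_langmuir(data.frame(conc_uM = c(1, 2, 4), delta_pct = c(1, 2, 3))),
    ">= 4"
  )
  expect_error(
    fit_langmuir(data.frame(conc_uM = c(1, 1, 2, 4), delta_pct = c(1, 1, 2, 3))),
    "unique"
  )
})

test_that("acceptance applies the Dmax >= 20% and CV < 20% thresholds", {
  mk_fit <- function(dmax, cv) {
    s <- data.frame(conc_uM = design_concs)
    s$delta_pct <- langmuir(s$conc_uM, 5, 30)
    f <- fit_langmuir(s)
    f$dmax_pct <- dmax
    f$dmax_se_pct <- dmax * cv / 100
    f$cv_dmax_pct <- cv
    apply_acceptance(f)
  }
  expect_true(mk_fit(35, 8)$accepted)
  rej1 <- mk_fit(15, 5)
  expect_false(rej1$accepted)
  expect_match(rej1$reason, "dmax")
  rej2 <- mk_fit(40, 25)
  expect_false(rej2$accepted)
  expect_match(rej2$reason, "cv")
})

test_that("parameter recovery and interval coverage meet the design targets", {
  # 200 seeded synthetic titrations: KD log-uniform [0.5, 50] uM, Dmax
  # uniform [20, 60]%, replicate noise 1 percentage point, n = 3, the
  # standard 8-concentration design
  set.seed(42)
  n_rep <- 3
  rel_err <- numeric(200)
  covered <- logical(200)
  for (i in 1:200) {
    kd <- exp(runif(1, log(0.5), log(50)))
    dmax <- runif(1, 20, 60)
    y <- vapply(design_concs, function(L) {
      mean(langmuir(L, kd, dmax) + rnorm(n_rep, 0, 1))
    }, numeric(1))
    f <- fit_langmuir(data.frame(conc_uM = design_concs, delta_pct = y))
    rel_err[i] <- abs(f$kd_uM - kd) / kd
    covered[i] <- abs(f$kd_uM - kd) <= 2 * f$kd_se_uM
  }
  expect_lt(median(rel_err), 0.15)
  expect_gte(mean(covered), 0.80)
  expect_lte(mean(covered), 0.99)
})

test_that("increasing noise never increases the accepted fraction", {
  accept_frac <- vapply(c(0.5, 2, 6), function(sigma) {
    set.seed(77)
    ok <- vapply(1:40, function(i) {
      y <- langmuir(design_concs, 5, 30) + rnorm(8, 0, sigma)
      isTRUE(fit_langmuir(
        data.frame(conc_uM = design_concs, delta_pct = y)
      )$accepted)
    }, logical(1))
    mean(ok)
  }, numeric(1))
  expect_true(all(diff(accept_frac) <= 0))
})

test_that("global aggregation reproduces the worked bromodomain example", {
  t2 <- example_peptide_kd()
  t2$accepted <- TRUE
  maximal <- global_kd(t2, "maximal")
  # mean and sample SD of the 40 printed values (hand-checked oracle)
  expect_equal(maximal$mean_kd_uM, mean(t2$kd_uM))
  expect_equal(maximal$mean_kd_uM, 5.395, tolerance = 1e-3)
  expect_equal(maximal$sd_kd_uM, sd(t2$kd_uM))
  expect_equal(maximal$n_peptides, 40L)

  ext <- kd_extremes(t2)
  expect_equal(unique(ext$min$kd_uM), 2.3)
  expect_true("72-80" %in% ext$min$target_id) # tied with 88-95
  expect_equal(ext$max$target_id, "42-49")
  expect_equal(ext$max$kd_uM, 30.5)

  # singleton behavior
  single <- global_kd(t2[1, ], "maximal")
  expect_equal(single$mean_kd_uM, t2$kd_uM[1])
  expect_equal(single$sd_kd_uM, 0)
  sx <- kd_extremes(t2[1, ])
  expect_equal(sx$min$kd_uM, sx$max$kd_uM)

  # extremes equal a brute-force linear scan
  expect_equal(min(t2$kd_uM), unique(ext$min$kd_uM))
  expect_equal(max(t2$kd_uM), unique(ext$max$kd_uM))
})

test_that("greedy minimal set covers exactly the accepted-peptide union", {
  t2 <- example_peptide_kd()
  t2$accepted <- TRUE
  gmin <- global_kd(t2, "minimal")
  union_all <- sort(unique(unlist(Map(seq, t2$start, t2$end))))
  union_min <- sort(unique(unlist(
    Map(seq, gmin$members$start, gmin$members$end)
  )))
  expect_identical(union_min, union_all)
  expect_lt(gmin$n_peptides, 10)
  expect_identical(gmin$n_peptides, length(gmin$member_ids))
  # minimal-mode mean stays close to the maximal-mode mean
  gmax <- global_kd(t2, "maximal")
  expect_lt(abs(gmin$mean_kd_uM - gmax$mean_kd_uM), 1.5)
  expect_error(global_kd(dplyr::mutate(t2, accepted = FALSE)), "no accepted")
})

test_that("labeling-time choice maximizes significant counts with |dD| ties", {
  mk_diff <- function(expo, n_sig, dsum) {
    tibble::tibble(
      sequence = paste0("P", seq_len(50)), start = seq_len(50),
      end = seq_len(50) + 9, exposure_min = expo, ligand_conc_uM = 20,
      delta_da = dsum / 50,
      significant = c(rep(TRUE, n_sig), rep(FALSE, 50 - n_sig))
    )
  }
  d <- dplyr::bind_rows(
    mk_diff(0.5, 10, 5), mk_diff(5, 40, 30), mk_diff(50, 25, 40)
  )
  pick <- choose_labeling_time(d)
  expect_equal(pick$exposure_min, 5)
  expect_equal(pick$diagnostics$n_significant, c(10, 40, 25))

  # tie on counts: larger summed |dD| wins; verify against brute force
  dt <- dplyr::bind_rows(mk_diff(0.5, 20, 12), mk_diff(5, 20, 30))
  expect_equal(choose_labeling_time(dt)$exposure_min, 5)
  diag <- choose_labeling_time(dt)$diagnostics
  brute <- diag$exposure_min[order(-diag$n_significant, -diag$sum_abs_delta_da)][1]
  expect_equal(choose_labeling_time(dt)$exposure_min, brute)

  # no significant peptide anywhere
  dn <- dplyr::bind_rows(mk_diff(0.5, 0, 1), mk_diff(5, 0, 2))
  expect_true(is.na(choose_labeling_time(dn)$exposure_min))
})

test_that("tidy and glance expose the fit in broom shape", {
  s <- data.frame(conc_uM = design_concs)
  s$delta_pct <- langmuir(s$conc_uM, 5, 30)
  f <- fit_langmuir(s, target_id = "18-33")
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(td$estimate[td$term == "kd_uM"], 5, tolerance = 1e-6)
  gl <- glance(f)
  expect_identical(gl$target_id, "18-33")
  expect_true(gl$accepted)
  expect_s3_class(autoplot(f), "ggplot")
})
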
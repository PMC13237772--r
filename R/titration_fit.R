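# Single-site Langmuir isotherm fitting of protection versus ligand
# concentration, acceptance rules (Dmax >= 20%, CV < 20%), and global K_D
# aggregation over maximal / minimal peptide sets.

#' Evaluate the single-site Langmuir isotherm
#'
#' \eqn{\Delta D(L) = \Delta D_{max} L / (K_D + L)}; the fitted value at
#' `L == kd` is exactly `dmax / 2` (half-saturation).
#'
#' @param conc_uM Ligand concentration(s), micromolar.
#' @param kd Dissociation constant, micromolar.
#' @param dmax Maximal protection (same units as the response).
#' @return Predicted protection.
#' @export
langmuir <- function(conc_uM, kd, dmax) {
  dmax * conc_uM / (kd + conc_uM)
}

# Initialization per the package's standard scheme: Dmax0 = max observed
# response; KD0 = the concentration whose response is nearest Dmax0/2,
# log-interpolated between bracketing points when possible.
langmuir_start <- function(conc, y) {
  dmax0 <- max(y)
  half <- dmax0 / 2
  ord <- order(conc)
  conc <- conc[ord]
  y <- y[ord]
  j <- which(y >= half)[1]
  kd0 <- if (!is.na(j) && j > 1 && y[j - 1] < half && y[j] > y[j - 1]) {
    # log-linear interpolation in concentration across the half-crossing
    f <- (half - y[j - 1]) / (y[j] - y[j - 1])
    exp(log(conc[j - 1]) + f * (log(conc[j]) - log(conc[j - 1])))
  } else {
    conc[which.min(abs(y - half))]
  }
  c(kd = max(kd0, 1e-3), dmax = max(dmax0, 1e-6))
}

#' Fit a titration series to the single-site Langmuir isotherm
#'
#' Minimizes \eqn{\sum_i (\Delta D_i - \Delta D_{max} L_i/(K_D+L_i))^2}
#' (unweighted by default) with bounded Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]). Standard errors come from the RSS-scaled
#' Gauss-Newton parameter covariance at the optimum; the coefficient of
#' variation of \eqn{\Delta D_{max}} is `100 * dmax_se / dmax`.
#'
#' @param series Data frame with columns `conc_uM` (strictly positive,
#'   unique, >= 4 values) and `delta_pct` (protection, percent of
#'   theoretical max uptake); optional `sd_pct` used when
#'   `weighting = "1/sd2"`.
#' @param weighting `"none"` (default) or `"1/sd2"`.
#' @param min_dmax_pct,max_cv_pct Acceptance thresholds applied by
#'   [apply_acceptance()] (defaults 20 and 20).
#' @param bounds Named list `kd = c(lo, hi)`, `dmax = c(lo, hi)` in uM / %;
#'   defaults keep the optimizer in physical territory while allowing noise
#'   overshoot.
#' @param target_id Optional identifier carried into tidy output.
#' @return Object of class `langmuir_fit` with fields `kd_uM`, `kd_se_uM`,
#'   `dmax_pct`, `dmax_se_pct`, `cv_dmax_pct`, `accepted`, `reason`,
#'   `residual_rss`, `n_points`, `converged`, `data`. Failed fits (including
#'   series with no positive protection) are returned with
#'   `converged = FALSE` and a diagnostic `reason`, never dropped silently.
#' @examples
#' s <- data.frame(conc_uM = c(0.95, 1.9, 3.8, 7.6, 15.2, 30.4, 60.8, 121.6))
#' s$delta_pct <- langmuir(s$conc_uM, kd = 5, dmax = 30)
#' fit_langmuir(s)
#' @export
fit_langmuir <- function(series, weighting = c("none", "1/sd2"),
                         min_dmax_pct = 20, max_cv_pct = 20,
                         bounds = list(kd = c(1e-3, 1e5), dmax = c(0, 150)),
                         target_id = NULL) {
  weighting <- match.arg(weighting)
  series <- tibble::as_tibble(series)
  conc <- series$conc_uM
  y <- series$delta_pct
  if (anyNA(conc) || anyNA(y)) stop("series contains NA", call. = FALSE)
  if (any(conc <= 0)) stop("concentrations must be strictly positive", call. = FALSE)
  if (anyDuplicated(conc)) stop("concentrations must be unique", call. = FALSE)
  if (length(conc) < 4) stop("need >= 4 distinct concentrations", call. = FALSE)

  failed <- function(reason) {
    structure(
      list(
        target_id = target_id, kd_uM = NA_real_, kd_se_uM = NA_real_,
        dmax_pct = NA_real_, dmax_se_pct = NA_real_,
        cv_dmax_pct = NA_real_, accepted = FALSE, reason = reason,
        residual_rss = NA_real_, n_points = length(conc),
        converged = FALSE, data = series,
        min_dmax_pct = min_dmax_pct, max_cv_pct = max_cv_pct
      ),
      class = "langmuir_fit"
    )
  }
  if (all(y <= 0)) {
    return(failed("no protection"))
  }

  w <- if (weighting == "1/sd2") {
    if (!"sd_pct" %in% names(series) || any(series$sd_pct <= 0)) {
      stop("weighting '1/sd2' needs strictly positive sd_pct", call. = FALSE)
    }
    1 / series$sd_pct^2
  } else {
    rep(1, length(y))
  }
  start <- langmuir_start(conc, y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ dmax * conc / (kd + conc),
      data = data.frame(conc = conc, y = y),
      start = list(kd = start[["kd"]], dmax = start[["dmax"]]),
      lower = c(bounds$kd[1], bounds$dmax[1]),
      upper = c(bounds$kd[2], bounds$dmax[2]),
      weights = w,
      control = minpack.lm::nls.lm.control(
        maxiter = 500, ftol = 1e-14, ptol = 1e-14
      )
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(failed(paste("fit failed:", conditionMessage(fit))))
  }
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA_real_, NA_real_))
  rss <- sum(stats::residuals(fit)^2)
  out <- structure(
    list(
      target_id = target_id,
      kd_uM = unname(est["kd"]), kd_se_uM = unname(se[1]),
      dmax_pct = unname(est["dmax"]), dmax_se_pct = unname(se[2]),
      cv_dmax_pct = 100 * unname(se[2]) / unname(est["dmax"]),
      accepted = NA, reason = NA_character_,
      residual_rss = rss, n_points = length(conc),
      converged = TRUE, data = series,
      min_dmax_pct = min_dmax_pct, max_cv_pct = max_cv_pct
    ),
    class = "langmuir_fit"
  )
  apply_acceptance(out, min_dmax_pct, max_cv_pct)
}

#' Apply the acceptance rule to a Langmuir fit
#'
#' A fitted K_D is accepted only if the maximal protection is at least
#' `min_dmax_pct` percent and the coefficient of variation of
#' \eqn{\Delta D_{max}} is below `max_cv_pct` percent.
#'
#' @param fit A `langmuir_fit`.
#' @param min_dmax_pct Minimum \eqn{\Delta D_{max}} in percent (default 20).
#' @param max_cv_pct Maximum CV of \eqn{\Delta D_{max}} in percent
#'   (default 20).
#' @return The fit with `accepted` and `reason` set.
#' @export
apply_acceptance <- function(fit, min_dmax_pct = 20, max_cv_pct = 20) {
  stopifnot(inherits(fit, "langmuir_fit"))
  fit$min_dmax_pct <- min_dmax_pct
  fit$max_cv_pct <- max_cv_pct
  if (!isTRUE(fit$converged)) {
    fit$accepted <- FALSE
    if (is.na(fit$reason)) fit$reason <- "fit failed"
    return(fit)
  }
  ok_dmax <- fit$dmax_pct >= min_dmax_pct
  ok_cv <- is.finite(fit$cv_dmax_pct) && fit$cv_dmax_pct < max_cv_pct
  fit$accepted <- ok_dmax && ok_cv
  fit$reason <- if (fit$accepted) {
    "accepted"
  } else if (!ok_dmax && !ok_cv) {
    "dmax below threshold; cv above threshold"
  } else if (!ok_dmax) {
    "dmax below threshold"
  } else {
    "cv above threshold"
  }
  fit
}

#' @export
print.langmuir_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<langmuir_fit> FAILED:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<langmuir_fit>%s K_D^app = %.3g +/- %.2g uM, Dmax = %.3g +/- %.2g %%, CV %.1f%%, %s\n",
    if (is.null(x$target_id)) "" else paste0(" [", x$target_id, "]"),
    x$kd_uM, x$kd_se_uM, x$dmax_pct, x$dmax_se_pct, x$cv_dmax_pct,
    if (isTRUE(x$accepted)) "accepted" else paste("rejected:", x$reason)
  ))
  invisible(x)
}

#' @rdname fit_langmuir
#' @param x A `langmuir_fit`.
#' @param ... Unused.
#' @method tidy langmuir_fit
#' @export
tidy.langmuir_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kd_uM", "dmax_pct"),
    estimate = c(x$kd_uM, x$dmax_pct),
    std.error = c(x$kd_se_uM, x$dmax_se_pct)
  )
}

#' @rdname fit_langmuir
#' @method glance langmuir_fit
#' @export
glance.langmuir_fit <- function(x, ...) {
  tibble::tibble(
    target_id = x$target_id %||% NA_character_,
    kd_uM = x$kd_uM, kd_se_uM = x$kd_se_uM,
    dmax_pct = x$dmax_pct, dmax_se_pct = x$dmax_se_pct,
    cv_pct = x$cv_dmax_pct, accepted = isTRUE(x$accepted),
    reason = x$reason, n_points = x$n_points, rss = x$residual_rss,
    converged = x$converged
  )
}

#' @rdname fit_langmuir
#' @param object A `langmuir_fit`.
#' @method autoplot langmuir_fit
#' @export
autoplot.langmuir_fit <- function(object, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$conc_uM, y = .data$delta_pct)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "ligand concentration (uM)", y = "protection (% of max uptake)",
      title = if (object$converged) {
        sprintf(
          "%s  K_D^app = %.2g +/- %.2g uM (%s)",
          object$target_id %||% "", object$kd_uM, object$kd_se_uM,
          if (isTRUE(object$accepted)) "accepted" else object$reason
        )
      } else {
        paste(object$target_id %||% "", object$reason)
      }
    ) +
    ggplot2::theme_minimal()
  if ("sd_pct" %in% names(d) && any(is.finite(d$sd_pct))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$delta_pct - .data$sd_pct,
        ymax = .data$delta_pct + .data$sd_pct
      ),
      width = 0.05
    )
  }
  if (object$converged) {
    grid <- tibble::tibble(
      conc_uM = exp(seq(log(min(d$conc_uM)), log(max(d$conc_uM)),
        length.out = 200
      ))
    )
    grid$delta_pct <- langmuir(grid$conc_uM, object$kd_uM, object$dmax_pct)
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  p
}

#' Fit every peptide titration in a differential table
#'
#' Filters one exposure, builds per-peptide series of protection versus
#' ligand concentration and fits each with [fit_langmuir()].
#'
#' @param diff Differential tibble from [delta_uptake()].
#' @param exposure_min Labeling time to fit at (default: the single exposure
#'   present; required when several are).
#' @inheritParams fit_langmuir
#' @param d_frac D2O mole fraction used to express pooled SDs on the percent
#'   scale (default 0.894).
#' @return Tibble, one row per peptide, with the columns of
#'   [glance.langmuir_fit()] plus `sequence`, `start`, `end`, and a
#'   list-column `fit` holding each `langmuir_fit`.
#' @export
fit_all_titrations <- function(diff, exposure_min = NULL,
                               weighting = "none",
                               min_dmax_pct = 20, max_cv_pct = 20,
                               d_frac = 0.894) {
  expos <- unique(diff$exposure_min)
  if (is.null(exposure_min)) {
    if (length(expos) > 1) {
      stop("several exposures present; pass `exposure_min`", call. = FALSE)
    }
    exposure_min <- expos
  }
  d <- dplyr::filter(diff, .data$exposure_min == .env$exposure_min)
  d |>
    dplyr::group_by(.data$sequence, .data$start, .data$end) |>
    dplyr::group_map(function(g, k) {
      id <- sprintf("%d-%d", k$start, k$end)
      series <- tibble::tibble(
        conc_uM = g$ligand_conc_uM, delta_pct = g$delta_pct,
        sd_pct = if ("pooled_sd" %in% names(g) && "n_exchangeable" %in% names(g)) {
          100 * g$pooled_sd / (g$n_exchangeable * d_frac)
        } else {
          NA_real_
        }
      )
      fit <- if (nrow(series) >= 4 && !anyNA(series$delta_pct)) {
        fit_langmuir(series,
          weighting = weighting, min_dmax_pct = min_dmax_pct,
          max_cv_pct = max_cv_pct, target_id = id
        )
      } else {
        NULL
      }
      row <- if (is.null(fit)) {
        tibble::tibble(
          target_id = id, kd_uM = NA_real_, kd_se_uM = NA_real_,
          dmax_pct = NA_real_, dmax_se_pct = NA_real_, cv_pct = NA_real_,
          accepted = FALSE, reason = "too few concentrations",
          n_points = nrow(series), rss = NA_real_, converged = FALSE
        )
      } else {
        glance(fit)
      }
      dplyr::bind_cols(k, row, tibble::tibble(fit = list(fit)))
    }) |>
    purrr::list_rbind()
}

#' Global apparent K_D over a set of accepted peptide fits
#'
#' Maximal mode averages every accepted fit. Minimal mode first selects a
#' small peptide subset by greedy weighted set cover — iteratively the
#' accepted peptide covering the most not-yet-covered residues (ties: lower
#' CV, then lower start) until the subset covers every residue any accepted
#' peptide covers — then averages the subset. SD is the sample SD (n - 1).
#'
#' @param fits Tibble with columns `start`, `end`, `kd_uM`, `accepted`
#'   (e.g. from [fit_all_titrations()] or [example_peptide_kd()] plus an
#'   `accepted` column); optional `cv_pct` used in tie-breaks.
#' @param mode `"maximal"` or `"minimal"`.
#' @return A list of class `global_kd`: `mode`, `mean_kd_uM`, `sd_kd_uM`,
#'   `n_peptides`, `member_ids` (as `"start-end"` labels), `members`
#'   (tibble).
#' @export
global_kd <- function(fits, mode = c("maximal", "minimal")) {
  mode <- match.arg(mode)
  acc <- dplyr::filter(tibble::as_tibble(fits), .data$accepted)
  if (nrow(acc) == 0) stop("no accepted fits", call. = FALSE)
  acc$target_id <- sprintf("%d-%d", acc$start, acc$end)
  members <- if (mode == "maximal") {
    acc
  } else {
    universe <- sort(unique(unlist(Map(seq, acc$start, acc$end))))
    chosen <- integer(0)
    covered <- integer(0)
    cv <- if ("cv_pct" %in% names(acc)) acc$cv_pct else rep(NA_real_, nrow(acc))
    cv_rank <- ifelse(is.na(cv), Inf, cv)
    while (length(setdiff(universe, covered)) > 0) {
      gain <- vapply(seq_len(nrow(acc)), function(i) {
        length(setdiff(seq(acc$start[i], acc$end[i]), covered))
      }, integer(1))
      gain[chosen] <- -1L
      best <- which(gain == max(gain))
      if (length(best) > 1) best <- best[order(cv_rank[best], acc$start[best])]
      pick <- best[1]
      chosen <- c(chosen, pick)
      covered <- union(covered, seq(acc$start[pick], acc$end[pick]))
    }
    acc[sort(chosen), ]
  }
  structure(
    list(
      mode = mode,
      mean_kd_uM = mean(members$kd_uM),
      sd_kd_uM = if (nrow(members) > 1) sd(members$kd_uM) else 0,
      n_peptides = nrow(members),
      member_ids = members$target_id,
      members = members
    ),
    class = "global_kd"
  )
}

#' @export
print.global_kd <- function(x, ...) {
  cat(sprintf(
    "<global_kd> %s mode: K_D^app = %.2f +/- %.2f uM over %d peptides\n",
    x$mode, x$mean_kd_uM, x$sd_kd_uM, x$n_peptides
  ))
  invisible(x)
}

#' @rdname global_kd
#' @param x A `global_kd`.
#' @param ... Unused.
#' @method glance global_kd
#' @export
glance.global_kd <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, mean_kd_uM = x$mean_kd_uM, sd_kd_uM = x$sd_kd_uM,
    n_peptides = x$n_peptides
  )
}

#' Extreme (tightest / weakest) accepted K_D values
#'
#' @param fits Tibble with `start`, `end`, `kd_uM`, `accepted`.
#' @return List with tibbles `min` and `max`; ties are reported in full.
#' @export
kd_extremes <- function(fits) {
  acc <- dplyr::filter(tibble::as_tibble(fits), .data$accepted)
  if (nrow(acc) == 0) stop("no accepted fits", call. = FALSE)
  acc$target_id <- sprintf("%d-%d", acc$start, acc$end)
  list(
    min = acc[acc$kd_uM == min(acc$kd_uM), ],
    max = acc[acc$kd_uM == max(acc$kd_uM), ]
  )
}

#' Choose the labeling time that maximizes measurable protection
#'
#' Picks the exposure with the greatest number of significant peptides; ties
#' are broken by the larger summed |delta D|.
#'
#' @param diff Differential tibble from [delta_uptake()] covering at least
#'   two exposures with significance verdicts.
#' @return A list: `exposure_min` (NA when no exposure has any significant
#'   peptide) and `diagnostics`, a tibble `exposure_min, n_significant,
#'   sum_abs_delta_da`.
#' @export
choose_labeling_time <- function(diff) {
  diag <- diff |>
    dplyr::group_by(.data$exposure_min) |>
    dplyr::summarise(
      n_significant = sum(.data$significant %in% TRUE),
      sum_abs_delta_da = sum(abs(.data$delta_da)), .groups = "drop"
    ) |>
    dplyr::arrange(
      dplyr::desc(.data$n_significant), dplyr::desc(.data$sum_abs_delta_da)
    )
  best <- if (all(diag$n_significant == 0)) NA_real_ else diag$exposure_min[1]
  list(exposure_min = best, diagnostics = dplyr::arrange(diag, .data$exposure_min))
}

#' Write fit results CSV
#'
#' Schema: `target_id,sequence,start,end,kd_uM,kd_se_uM,dmax_pct,
#' dmax_se_pct,cv_pct,accepted,reason,n_points,rss`.
#'
#' @param fits Fit-results tibble from [fit_all_titrations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_results <- function(fits, path) {
  cols <- c(
    "target_id", "sequence", "start", "end", "kd_uM", "kd_se_uM",
    "dmax_pct", "dmax_se_pct", "cv_pct", "accepted", "reason",
    "n_points", "rss"
  )
  readr::write_csv(fits[intersect(cols, names(fits))], path, progress = FALSE)
  invisible(path)
}
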
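# Apo-versus-liganded differential uptake (protection), the hybrid
# significance criterion (>5% and >0.5 Da and Welch t-test p < 0.05),
# per-peptide time-sum aggregation, and replicate-quality metrics.

#' Significance criteria for differential uptake
#'
#' The hybrid criterion: a difference is significant only if it exceeds
#' `min_pct` percent of the theoretical maximum uptake AND `min_da` Da AND
#' passes a two-sided t-test at level `alpha`.
#'
#' @param min_pct Minimum percent difference (default 5).
#' @param min_da Minimum absolute difference in Da (default 0.5).
#' @param alpha Test level (default 0.05).
#' @return A list of class `significance_criteria`.
#' @export
significance_criteria <- function(min_pct = 5, min_da = 0.5, alpha = 0.05) {
  if (min_pct <= 0 || min_da <= 0 || alpha <= 0 || alpha >= 1) {
    stop("criteria must be strictly positive with alpha in (0, 1)",
      call. = FALSE
    )
  }
  structure(list(min_pct = min_pct, min_da = min_da, alpha = alpha),
    class = "significance_criteria"
  )
}

# Welch two-sided p-value with degenerate-variance handling.
welch_p <- function(a, b, pooled = FALSE) {
  if (length(a) < 2 || length(b) < 2) {
    return(NA_real_)
  }
  if (sd(a) == 0 && sd(b) == 0) {
    # zero variance in both groups: p = 0 for any nonzero difference
    return(if (mean(a) == mean(b)) 1 else 0)
  }
  stats::t.test(a, b, var.equal = pooled)$p.value
}

#' Differential uptake between apo and liganded states
#'
#' For every (peptide, exposure, ligand concentration) group, computes the
#' protection `delta_da = mean(apo) - mean(bound)` (positive = protection),
#' its percent of the theoretical maximum uptake
#' (`n_exchangeable * d_frac`), the propagated pooled standard error
#' `sqrt(sd_apo^2/n_apo + sd_bound^2/n_bound)`, a two-sided Welch t-test
#' p-value, and the hybrid significance verdict.
#'
#' @param uptake Uptake tibble (see [read_uptake_table()]): columns
#'   `sequence, start, end, state, ligand_conc_uM, exposure_min, replicate,
#'   uptake_da, n_exchangeable`.
#' @param d_frac D2O mole fraction during labeling (default 0.894).
#' @param criteria A [significance_criteria()].
#' @param pooled_var Use pooled-variance Student's test instead of Welch
#'   (default FALSE).
#' @param percent_of Denominator for the percent criterion:
#'   `"theoretical_max"` (default, `n_exchangeable * d_frac`) or
#'   `"apo_uptake"`.
#' @param p_adjust Multiple-testing adjustment passed to
#'   [stats::p.adjust()] (default `"none"`, matching the per-peptide hybrid
#'   criterion; `"BH"` available).
#' @return Tibble with one row per (peptide, exposure, concentration):
#'   `sequence, start, end, exposure_min, ligand_conc_uM, n_apo, n_bound,
#'   delta_da, delta_pct, pooled_sd, p_value, significant`. Peptides with no
#'   observable amides get `delta_pct = NA` and are flagged
#'   (`percent_undefined`); fewer than 2 replicates per state gives
#'   `p_value = NA` and `significant = NA` (untestable).
#' @export
delta_uptake <- function(uptake, d_frac = 0.894,
                         criteria = significance_criteria(),
                         pooled_var = FALSE,
                         percent_of = c("theoretical_max", "apo_uptake"),
                         p_adjust = "none") {
  percent_of <- match.arg(percent_of)
  apo <- dplyr::filter(uptake, .data$ligand_conc_uM == 0)
  bound <- dplyr::filter(uptake, .data$ligand_conc_uM > 0)
  if (nrow(apo) == 0 || nrow(bound) == 0) {
    stop("need at least one apo and one liganded record", call. = FALSE)
  }
  key <- c("sequence", "start", "end", "n_exchangeable", "exposure_min")
  apo_g <- apo |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
    dplyr::summarise(
      apo_vals = list(.data$uptake_da), .groups = "drop"
    )
  out <- bound |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(key, "ligand_conc_uM")))) |>
    dplyr::summarise(bound_vals = list(.data$uptake_da), .groups = "drop") |>
    dplyr::inner_join(apo_g, by = key)
  res <- purrr::pmap(
    list(out$apo_vals, out$bound_vals, out$n_exchangeable),
    function(a, b, nex) {
      max_up <- nex * d_frac
      dd <- mean(a) - mean(b)
      dpct <- if (percent_of == "theoretical_max") {
        if (nex == 0) NA_real_ else 100 * dd / max_up
      } else {
        if (mean(a) == 0) NA_real_ else 100 * dd / mean(a)
      }
      psd <- sqrt(
        (if (length(a) > 1) sd(a)^2 else 0) / length(a) +
          (if (length(b) > 1) sd(b)^2 else 0) / length(b)
      )
      tibble::tibble(
        n_apo = length(a), n_bound = length(b),
        delta_da = dd, delta_pct = dpct, pooled_sd = psd,
        p_value = welch_p(a, b, pooled = pooled_var),
        percent_undefined = is.na(dpct)
      )
    }
  ) |> purrr::list_rbind()
  out <- dplyr::bind_cols(
    dplyr::select(out, -dplyr::all_of(c("apo_vals", "bound_vals"))), res
  )
  if (p_adjust != "none") {
    out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  }
  out$significant <- with(out, ifelse(
    is.na(p_value) | is.na(delta_pct), NA,
    abs(delta_pct) > criteria$min_pct &
      abs(delta_da) > criteria$min_da &
      p_value < criteria$alpha
  ))
  dplyr::arrange(out, .data$start, .data$end, .data$exposure_min, .data$ligand_conc_uM)
}

#' Sum differential uptake across exposures per peptide
#'
#' The "SUM" aggregate: the arithmetic sum of `delta_da` over exposure times
#' for each peptide (at a fixed ligand concentration), a robust single-number
#' summary of total protection.
#'
#' @param diff Differential tibble from [delta_uptake()].
#' @return Tibble `sequence, start, end, ligand_conc_uM, sum_delta_da,
#'   n_exposures`.
#' @export
sum_differences <- function(diff) {
  dup <- diff |>
    dplyr::count(
      .data$sequence, .data$start, .data$end, .data$ligand_conc_uM,
      .data$exposure_min
    ) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate (peptide, exposure) pairs in differential table",
      call. = FALSE
    )
  }
  diff |>
    dplyr::group_by(
      .data$sequence, .data$start, .data$end, .data$ligand_conc_uM
    ) |>
    dplyr::summarise(
      sum_delta_da = sum(.data$delta_da),
      n_exposures = dplyr::n(), .groups = "drop"
    )
}

#' Replicate-quality metric (mean relative replicate SD)
#'
#' For every (peptide, state, exposure) group with at least two replicates,
#' the replicate standard deviation is expressed as a percentage of the
#' theoretical maximum uptake (`n_exchangeable * d_frac`); the metric is the
#' mean over groups. This is one reasonable reading of a "replicability"
#' percentage; no single field-standard formula exists, so the value should
#' be compared only against itself across runs.
#'
#' @param uptake Uptake tibble.
#' @param d_frac D2O mole fraction (default 0.894).
#' @return Replicability as a percentage (scalar).
#' @export
replicability <- function(uptake, d_frac = 0.894) {
  g <- uptake |>
    dplyr::group_by(
      .data$sequence, .data$start, .data$end, .data$n_exchangeable,
      .data$state, .data$exposure_min
    ) |>
    dplyr::summarise(
      n = dplyr::n(), rep_sd = sd(.data$uptake_da), .groups = "drop"
    ) |>
    dplyr::filter(.data$n >= 2, .data$n_exchangeable > 0)
  if (nrow(g) == 0) stop("no replicated group", call. = FALSE)
  mean(100 * g$rep_sd / (g$n_exchangeable * d_frac))
}

#' Write the differential CSV
#'
#' Schema: `sequence,start,end,exposure_min,ligand_conc_uM,delta_da,
#' delta_pct,pooled_sd,p_value,significant`.
#'
#' @param diff Differential tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_differential <- function(diff, path) {
  cols <- c(
    "sequence", "start", "end", "exposure_min", "ligand_conc_uM",
    "delta_da", "delta_pct", "pooled_sd", "p_value", "significant"
  )
  readr::write_csv(diff[intersect(cols, names(diff))], path, progress = FALSE)
  invisible(path)
}
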
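# Pipeline-stage report functions: each reads tabular inputs, runs the
# corresponding analysis stage, writes the data-of-record CSVs, and returns
# the result tibbles. Plots are artifacts; every number in them is
# re-derivable from the CSVs. A thin command-line wrapper over these
# functions ships at inst/cli/hdxkd.R.

#' Validate a run configuration
#'
#' @param config Named list. Recognized keys: `uptake_table`,
#'   `fragment_table`, `column_map`, `state_map`, `d_frac`,
#'   `back_exchange_factor`, `criteria` (list `min_pct`, `min_da`, `alpha`),
#'   `fit` (list `weighting`, `min_dmax_pct`, `max_cv_pct`,
#'   `exposure_min`), `global` (list `mode`), `out_dir`, `seed`.
#'   Unknown keys are rejected.
#' @return The config with defaults filled, classed `hdx_config`.
#' @export
hdx_config <- function(config = list()) {
  known <- c(
    "uptake_table", "fragment_table", "column_map", "state_map",
    "d_frac", "back_exchange_factor", "criteria", "fit", "global",
    "out_dir", "seed"
  )
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  defaults <- list(
    d_frac = 0.894, back_exchange_factor = 1,
    criteria = list(min_pct = 5, min_da = 0.5, alpha = 0.05),
    fit = list(
      weighting = "none", min_dmax_pct = 20, max_cv_pct = 20,
      exposure_min = NULL
    ),
    global = list(mode = "maximal"),
    out_dir = ".", seed = 1L
  )
  for (k in names(defaults)) {
    if (is.null(config[[k]])) {
      config[[k]] <- defaults[[k]]
    } else if (is.list(defaults[[k]])) {
      for (kk in names(defaults[[k]])) {
        if (is.null(config[[k]][[kk]])) config[[k]][[kk]] <- defaults[[k]][[kk]]
      }
    }
  }
  structure(config, class = "hdx_config")
}

#' Differential-analysis report
#'
#' Reads the uptake table, computes differential uptake with the hybrid
#' significance criterion, writes `differential.csv` and per-peptide
#' uptake-vs-time plots (apo vs bound, SD error bars, significance stars).
#'
#' @param config An [hdx_config()] (or plain list).
#' @param plots Write plot files (default TRUE).
#' @return The differential tibble, invisibly with attribute `files`.
#' @export
report_diff <- function(config, plots = TRUE) {
  cfg <- if (inherits(config, "hdx_config")) config else hdx_config(config)
  up <- read_uptake_table(cfg$uptake_table, cfg$column_map, cfg$state_map)
  crit <- do.call(significance_criteria, cfg$criteria)
  diff <- delta_uptake(up, d_frac = cfg$d_frac, criteria = crit)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(cfg$out_dir, "differential.csv")
  write_differential(diff, csv)
  files <- csv
  if (plots) {
    peps <- dplyr::distinct(up, .data$sequence, .data$start, .data$end)
    for (i in seq_len(nrow(peps))) {
      p <- plot_uptake(up, peps$start[i], peps$end[i], diff = diff)
      f <- file.path(
        cfg$out_dir, sprintf("uptake_%d-%d.png", peps$start[i], peps$end[i])
      )
      ggplot2::ggsave(f, p, width = 5, height = 4, dpi = 120)
      files <- c(files, f)
    }
  }
  n_sig <- sum(diff$significant %in% TRUE)
  message(sprintf(
    "differential: %d records, %d significant", nrow(diff), n_sig
  ))
  attr(diff, "files") <- files
  invisible(diff)
}

#' Per-peptide uptake-vs-time plot
#'
#' @param uptake Uptake tibble.
#' @param start,end Peptide coordinates.
#' @param diff Optional differential tibble for significance stars.
#' @return A ggplot.
#' @export
plot_uptake <- function(uptake, start, end, diff = NULL) {
  d <- uptake |>
    dplyr::filter(.data$start == .env$start, .data$end == .env$end) |>
    dplyr::group_by(.data$state, .data$ligand_conc_uM, .data$exposure_min) |>
    dplyr::summarise(
      mean_da = mean(.data$uptake_da),
      sd_da = if (dplyr::n() > 1) sd(.data$uptake_da) else 0,
      .groups = "drop"
    )
  p <- ggplot2::ggplot(d, ggplot2::aes(
    x = .data$exposure_min, y = .data$mean_da,
    colour = .data$state, group = .data$state
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_da - .data$sd_da,
        ymax = .data$mean_da + .data$sd_da
      ),
      width = 0.05
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "exposure (min)", y = "uptake (Da)",
      title = sprintf("peptide %d-%d", start, end)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(diff)) {
    stars <- diff |>
      dplyr::filter(
        .data$start == .env$start, .data$end == .env$end,
        .data$significant %in% TRUE
      )
    if (nrow(stars) > 0) {
      ymax <- max(d$mean_da + d$sd_da)
      p <- p + ggplot2::annotate(
        "text",
        x = unique(stars$exposure_min), y = ymax * 1.05, label = "*"
      )
    }
  }
  p
}

#' Titration-fitting report
#'
#' Computes differential uptake across the titration, fits every peptide
#' with [fit_langmuir()], writes `fits.csv`, binding-curve plots for
#' accepted fits, and the global K_D summary in both maximal and minimal
#' modes.
#'
#' @param config An [hdx_config()].
#' @param plots Write plot files (default TRUE).
#' @return A list `fits` (tibble), `global` (tibble over both modes),
#'   invisibly.
#' @export
report_fit <- function(config, plots = TRUE) {
  cfg <- if (inherits(config, "hdx_config")) config else hdx_config(config)
  up <- read_uptake_table(cfg$uptake_table, cfg$column_map, cfg$state_map)
  crit <- do.call(significance_criteria, cfg$criteria)
  diff <- delta_uptake(up, d_frac = cfg$d_frac, criteria = crit)
  nconc <- length(unique(diff$ligand_conc_uM))
  if (nconc < 4) {
    stop("need differential records over >= 4 concentrations", call. = FALSE)
  }
  fits <- fit_all_titrations(
    diff,
    exposure_min = cfg$fit$exposure_min,
    weighting = cfg$fit$weighting,
    min_dmax_pct = cfg$fit$min_dmax_pct,
    max_cv_pct = cfg$fit$max_cv_pct,
    d_frac = cfg$d_frac
  )
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fit_results(fits, file.path(cfg$out_dir, "fits.csv"))
  glob <- NULL
  if (any(fits$accepted)) {
    glob <- dplyr::bind_rows(
      glance(global_kd(fits, "maximal")),
      glance(global_kd(fits, "minimal"))
    )
    readr::write_csv(glob, file.path(cfg$out_dir, "global_kd.csv"),
      progress = FALSE
    )
    gmin <- global_kd(fits, "minimal")
    message(
      "minimal-mode members: ", paste(gmin$member_ids, collapse = ", ")
    )
  } else {
    message("no accepted fits")
  }
  if (plots) {
    for (i in which(fits$accepted)) {
      f <- fits$fit[[i]]
      ggplot2::ggsave(
        file.path(cfg$out_dir, sprintf("fit_%s.png", fits$target_id[i])),
        autoplot(f),
        width = 5, height = 4, dpi = 120
      )
    }
  }
  invisible(list(fits = fits, global = glob))
}

#' Residue-level report
#'
#' Resolves fragment ladders across the titration into residue-level
#' deuteration, fits per-residue isotherms, writes `residues.csv` and a
#' per-residue K_D bar map with proline/segment annotations.
#'
#' @param config An [hdx_config()] with `fragment_table` set.
#' @param plots Write plot files (default TRUE).
#' @return The residue results tibble, invisibly.
#' @export
report_residues <- function(config, plots = TRUE) {
  cfg <- if (inherits(config, "hdx_config")) config else hdx_config(config)
  frag <- read_fragment_table(cfg$fragment_table)
  st <- parse_state_label(frag$state, cfg$state_map)
  frag$ligand_conc_uM <- st$ligand_conc_uM
  seqs <- unique(frag$sequence)
  res <- purrr::map(seqs, function(sq) {
    fr <- dplyr::filter(frag, .data$sequence == sq)
    mk <- function(d) {
      fragment_ladder(
        d[c(
          "ion_type", "ion_index", "charge", "centroid_mz_undeut",
          "centroid_mz_deut"
        )],
        sq,
        state = d$state[1]
      )
    }
    apo <- dplyr::filter(fr, .data$ligand_conc_uM == 0)
    if (nrow(apo) == 0) stop("no apo ladder for ", sq, call. = FALSE)
    concs <- sort(unique(fr$ligand_conc_uM[fr$ligand_conc_uM > 0]))
    ladders <- purrr::map(concs, function(cc) {
      mk(dplyr::filter(fr, .data$ligand_conc_uM == cc))
    })
    out <- residue_titration(ladders, mk(apo),
      conc_uM = concs,
      d_frac = cfg$d_frac, min_dmax_pct = cfg$fit$min_dmax_pct,
      max_cv_pct = cfg$fit$max_cv_pct
    )
    dplyr::mutate(out, sequence = sq, .before = 1)
  }) |> purrr::list_rbind()
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_residue_results(res, file.path(cfg$out_dir, "residues.csv"))
  if (plots && nrow(res) > 0) {
    p <- plot_residue_kd(res)
    ggplot2::ggsave(file.path(cfg$out_dir, "residue_kd.png"), p,
      width = 6, height = 4, dpi = 120
    )
  }
  invisible(res)
}

#' Per-residue K_D bar map
#'
#' @param res Residue results tibble from [residue_titration()].
#' @return A ggplot: accepted residue-level K_D values as bars, segments
#'   and prolines annotated.
#' @export
plot_residue_kd <- function(res) {
  d <- dplyr::filter(res, .data$kind == "resolved", .data$accepted)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$residue), y = .data$kd_uM)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$kd_uM - .data$kd_se_uM,
        ymax = .data$kd_uM + .data$kd_se_uM
      ),
      width = 0.3
    ) +
    ggplot2::labs(
      x = "residue (peptide position)", y = "K_D^app (uM)",
      caption = "prolines and N-terminal residues are not observable"
    ) +
    ggplot2::theme_minimal()
}

#' Scrambling-QC report
#'
#' Runs the available scrambling controls and writes one report row per
#' method to `qc.csv`.
#'
#' @param p1 Optional list `ladder` (a [fragment_ladder()]), `site_d`,
#'   optional `threshold_pct`.
#' @param ammonia Optional list `d_rs`, `d_rs_nh3`, `pooled_sd`, optional
#'   `threshold_da`.
#' @param out_dir Output directory (default ".").
#' @return Tibble `method, metric, value, threshold, flagged`, invisibly.
#' @export
report_qc <- function(p1 = NULL, ammonia = NULL, out_dir = ".") {
  if (is.null(p1) && is.null(ammonia)) {
    stop("no QC inputs: provide `p1` and/or `ammonia`", call. = FALSE)
  }
  rows <- list()
  if (!is.null(p1)) {
    r <- scrambling_p1(
      p1$ladder, p1$site_d,
      threshold_pct = p1$threshold_pct %||% 10
    )
    rows[[length(rows) + 1]] <- tibble::tibble(
      method = "p1", metric = "scrambling_pct", value = r$scrambling_pct,
      threshold = r$threshold, flagged = r$flagged
    )
  }
  if (!is.null(ammonia)) {
    r <- ammonia_loss_check(
      ammonia$d_rs, ammonia$d_rs_nh3,
      ammonia$pooled_sd %||% 0, ammonia$threshold_da %||% 0.1
    )
    rows[[length(rows) + 1]] <- tibble::tibble(
      method = "ammonia_loss", metric = "d_difference_da",
      value = r$d_difference_da, threshold = r$threshold,
      flagged = r$flagged
    )
  }
  out <- purrr::list_rbind(rows)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(out, file.path(out_dir, "qc.csv"), progress = FALSE)
  for (i in seq_len(nrow(out))) {
    message(sprintf(
      "qc %s: %s = %.3f (threshold %.3f) — %s",
      out$method[i], out$metric[i], out$value[i], out$threshold[i],
      if (out$flagged[i]) "FLAGGED" else "pass"
    ))
  }
  invisible(out)
}
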
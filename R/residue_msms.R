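# Residue-level deuteration from ECD c/z fragment-ion ladders, per-residue
# titration fitting, and hydrogen-scrambling quality control.
#
# Fragment-to-amide bookkeeping (the critical convention):
#
#   peptide   L  E  K  Q  Q  S  A  W ...      residue (peptide position) j
#   c series  c1 c2 c3 ...                    d(c_j) = sum of amide D of
#                                             observable residues 1..j —
#                                             the amide of residue j enters
#                                             c_j, NOT c_{j-1}
#   z series  ... z2 z1                       d(z_k) = sum of amide D of
#                                             observable residues n-k+1..n
#
# so residue j is resolved from consecutive c ions as d(c_j) - d(c_{j-1}),
# and from consecutive z ions as d(z_k) - d(z_{k-1}) with j = n - k + 1.
# Residues 1-2 (no measured amide / fast back-exchange) and prolines are
# never resolved; gaps in a series yield segment-level values.

#' Build a fragment ladder from a fragment-ion centroid table
#'
#' @param ions Data frame with columns `ion_type` ("c" or "z"), `ion_index`,
#'   `charge`, `centroid_mz_undeut`, `centroid_mz_deut`; optional `sd`.
#' @param sequence Precursor peptide sequence.
#' @param precursor_d Precursor deuterium content in Da (optional, used for
#'   conservation checks and C-terminal remainders).
#' @param state,exposure_min Optional labels carried along.
#' @return A list of class `fragment_ladder` with the per-ion deuterium
#'   contents `d_content = charge * (centroid_deut - centroid_undeut)`.
#' @export
fragment_ladder <- function(ions, sequence, precursor_d = NA_real_,
                            state = NA_character_, exposure_min = NA_real_) {
  ions <- tibble::as_tibble(ions)
  req <- c("ion_type", "ion_index", "charge", "centroid_mz_undeut", "centroid_mz_deut")
  miss <- setdiff(req, names(ions))
  if (length(miss) > 0) {
    stop("fragment table lacks column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  aa <- validate_sequence(sequence)
  n <- length(aa)
  if (any(!ions$ion_type %in% c("c", "z"))) {
    stop("ion_type must be 'c' or 'z'", call. = FALSE)
  }
  if (any(ions$ion_index >= n) || any(ions$ion_index < 1)) {
    stop("ion index must lie in [1, precursor length - 1]", call. = FALSE)
  }
  if (anyDuplicated(ions[c("ion_type", "ion_index", "charge")])) {
    stop("duplicate (ion_type, ion_index, charge) rows", call. = FALSE)
  }
  if (!"sd" %in% names(ions)) ions$sd <- 0
  ions$d_content <- ions$charge * (ions$centroid_mz_deut - ions$centroid_mz_undeut)
  structure(
    list(
      sequence = paste(aa, collapse = ""), n = n, ions = ions,
      precursor_d = precursor_d, state = state, exposure_min = exposure_min
    ),
    class = "fragment_ladder"
  )
}

#' @export
print.fragment_ladder <- function(x, ...) {
  cat(
    "<fragment_ladder> ", x$sequence, ": ",
    sum(x$ions$ion_type == "c"), " c ions, ",
    sum(x$ions$ion_type == "z"), " z ions",
    if (!is.na(x$precursor_d)) sprintf(", precursor %.3f Da", x$precursor_d),
    "\n",
    sep = ""
  )
  invisible(x)
}

# Resolve one ion series into residue/segment deuteration. Returns a tibble
# residue, kind, d_da, sd_da, segment_start, segment_end. `series_pos(k)`
# maps ion index to the highest peptide position the ion covers.
resolve_series <- function(idx, d, sds, n, from_nterm) {
  # Work in cumulative coordinates: for c ions, cum(j) = d(c_j); for z ions
  # define cum(j) = precursor-like cumulative from the N terminus via
  # cum(j) = d(z_n-j) reversed. Simpler: convert z_k to "covers positions
  # n-k+1..n"; a difference z_k - z_{k-1} isolates position n-k+1.
  ord <- order(idx)
  idx <- idx[ord]
  d <- d[ord]
  sds <- sds[ord]
  out <- list()
  # leading segment from the series origin to the first ion
  first_span <- if (from_nterm) c(1L, idx[1]) else c(n - idx[1] + 1L, n)
  out[[length(out) + 1]] <- tibble::tibble(
    span_start = first_span[1], span_end = first_span[2],
    d_da = d[1], sd_da = sds[1]
  )
  if (length(idx) > 1) {
    for (i in 2:length(idx)) {
      dd <- d[i] - d[i - 1]
      sdd <- sqrt(sds[i]^2 + sds[i - 1]^2)
      span <- if (from_nterm) {
        c(idx[i - 1] + 1L, idx[i])
      } else {
        c(n - idx[i] + 1L, n - idx[i - 1])
      }
      out[[length(out) + 1]] <- tibble::tibble(
        span_start = span[1], span_end = span[2], d_da = dd, sd_da = sdd
      )
    }
  }
  purrr::list_rbind(out)
}

#' Resolve a fragment ladder into residue-level deuteration
#'
#' Consecutive ions of one series localize deuterium to single residues;
#' gaps yield segment-level values. When both the c and the z series resolve
#' a residue the inverse-variance-weighted mean is reported (with a conflict
#' flag when the two disagree beyond 3 pooled SDs). Prolines and the two
#' N-terminal residues are emitted with their exclusion kinds and zero
#' deuterium. When `precursor_d` is known, the C-terminal remainder beyond
#' the last c ion (or N-terminal remainder beyond the last z ion) is
#' reported as a segment, so the emitted partition conserves the precursor
#' deuterium.
#'
#' @param ladder A [fragment_ladder()].
#' @param conflict_sigma Flag threshold for c/z disagreement (default 3).
#' @return Tibble `residue` (peptide position), `kind` (`resolved`,
#'   `segment`, `proline`, `excluded_nterm`), `d_da`, `sd_da`,
#'   `segment_start`, `segment_end`, `conflict`.
#' @export
ladder_to_residues <- function(ladder, conflict_sigma = 3) {
  stopifnot(inherits(ladder, "fragment_ladder"))
  n <- ladder$n
  aa <- strsplit(ladder$sequence, "")[[1]]
  obs <- observable_positions(ladder$sequence)

  spans_of <- function(type) {
    ions <- ladder$ions[ladder$ions$ion_type == type, , drop = FALSE]
    if (nrow(ions) == 0) {
      return(NULL)
    }
    # collapse charge states of the same index by inverse-variance mean
    ions <- ions |>
      dplyr::group_by(.data$ion_index) |>
      dplyr::summarise(
        d = if (all(.data$sd > 0)) {
          sum(.data$d_content / .data$sd^2) / sum(1 / .data$sd^2)
        } else {
          mean(.data$d_content)
        },
        sd = if (all(.data$sd > 0)) sqrt(1 / sum(1 / .data$sd^2)) else mean(.data$sd),
        .groups = "drop"
      )
    sp <- resolve_series(ions$ion_index, ions$d, ions$sd, n,
      from_nterm = (type == "c")
    )
    # remainder to the far end, when the precursor deuterium is known
    if (!is.na(ladder$precursor_d)) {
      if (type == "c") {
        last <- max(ions$ion_index)
        if (last < n) {
          sp <- dplyr::bind_rows(sp, tibble::tibble(
            span_start = last + 1L, span_end = n,
            d_da = ladder$precursor_d - ions$d[which.max(ions$ion_index)],
            sd_da = ions$sd[which.max(ions$ion_index)]
          ))
        }
      } else {
        last <- max(ions$ion_index)
        if (last < n) {
          sp <- dplyr::bind_rows(sp, tibble::tibble(
            span_start = 1L, span_end = n - last,
            d_da = ladder$precursor_d - ions$d[which.max(ions$ion_index)],
            sd_da = ions$sd[which.max(ions$ion_index)]
          ))
        }
      }
    }
    sp
  }

  # classify a span: how many observable amides does it contain?
  classify <- function(sp) {
    if (is.null(sp)) {
      return(NULL)
    }
    sp$n_obs <- vapply(seq_len(nrow(sp)), function(i) {
      sum(obs >= sp$span_start[i] & obs <= sp$span_end[i])
    }, integer(1))
    sp
  }

  c_sp <- classify(spans_of("c"))
  z_sp <- classify(spans_of("z"))

  # single-residue resolutions per series: spans containing exactly one
  # observable amide resolve that amide
  singles <- function(sp, series) {
    if (is.null(sp)) {
      return(NULL)
    }
    one <- sp[sp$n_obs == 1, , drop = FALSE]
    if (nrow(one) == 0) {
      return(NULL)
    }
    one$residue <- vapply(seq_len(nrow(one)), function(i) {
      obs[obs >= one$span_start[i] & obs <= one$span_end[i]]
    }, integer(1))
    one$series <- series
    one
  }
  res_c <- singles(c_sp, "c")
  res_z <- singles(z_sp, "z")
  resolved <- dplyr::bind_rows(res_c, res_z)

  out <- list()
  if (!is.null(resolved) && nrow(resolved) > 0) {
    out[[length(out) + 1]] <- resolved |>
      dplyr::group_by(.data$residue) |>
      dplyr::summarise(
        d_da = if (all(.data$sd_da > 0)) {
          sum(.data$d_da / .data$sd_da^2) / sum(1 / .data$sd_da^2)
        } else {
          mean(.data$d_da)
        },
        sd_da = if (all(.data$sd_da > 0)) {
          sqrt(1 / sum(1 / .data$sd_da^2))
        } else {
          max(.data$sd_da)
        },
        conflict = dplyr::n() > 1 &&
          abs(diff(range(.data$d_da))) >
            conflict_sigma * max(sqrt(sum(.data$sd_da^2)), 1e-12),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        kind = "resolved",
        segment_start = NA_integer_, segment_end = NA_integer_
      )
  }

  # multi-amide spans become segments over their *unresolved* amides: the
  # deuterium of amides already resolved inside the span is subtracted, and
  # segments are greedily selected (fewest unresolved amides first) so the
  # emitted spans are disjoint
  resolved_tbl <- if (length(out) > 0) out[[1]] else NULL
  resolved_res <- if (is.null(resolved_tbl)) integer(0) else resolved_tbl$residue
  seg_src <- dplyr::bind_rows(
    if (!is.null(c_sp)) c_sp[c_sp$n_obs > 1, ],
    if (!is.null(z_sp)) z_sp[z_sp$n_obs > 1, ]
  )
  if (nrow(seg_src) > 0) {
    cands <- purrr::map(seq_len(nrow(seg_src)), function(i) {
      amides <- obs[obs >= seg_src$span_start[i] & obs <= seg_src$span_end[i]]
      inside <- intersect(amides, resolved_res)
      open <- setdiff(amides, resolved_res)
      if (length(open) == 0) {
        return(NULL)
      }
      ri <- match(inside, resolved_tbl$residue)
      tibble::tibble(
        d_da = seg_src$d_da[i] -
          (if (length(inside) > 0) sum(resolved_tbl$d_da[ri]) else 0),
        sd_da = sqrt(seg_src$sd_da[i]^2 +
          (if (length(inside) > 0) sum(resolved_tbl$sd_da[ri]^2) else 0)),
        segment_start = min(open), segment_end = max(open),
        n_open = length(open), amides = list(open)
      )
    }) |> purrr::list_rbind()
    if (!is.null(cands) && nrow(cands) > 0) {
      cands <- cands[order(cands$n_open, cands$segment_end - cands$segment_start), ]
      taken <- integer(0)
      keep <- logical(nrow(cands))
      for (i in seq_len(nrow(cands))) {
        if (length(intersect(cands$amides[[i]], taken)) == 0) {
          keep[i] <- TRUE
          taken <- c(taken, cands$amides[[i]])
        }
      }
      cands <- cands[keep, , drop = FALSE]
      if (nrow(cands) > 0) {
        out[[length(out) + 1]] <- tibble::tibble(
          residue = NA_integer_, d_da = cands$d_da, sd_da = cands$sd_da,
          conflict = FALSE, kind = "segment",
          segment_start = cands$segment_start, segment_end = cands$segment_end
        )
      }
    }
  }

  # exclusion entries
  excl <- tibble::tibble(
    residue = seq_len(n),
    kind = dplyr::case_when(
      seq_len(n) <= 2 ~ "excluded_nterm",
      aa == "P" ~ "proline",
      TRUE ~ NA_character_
    )
  ) |> dplyr::filter(!is.na(.data$kind))
  out[[length(out) + 1]] <- dplyr::mutate(excl,
    d_da = 0, sd_da = 0, conflict = FALSE,
    segment_start = NA_integer_, segment_end = NA_integer_
  )

  res <- purrr::list_rbind(out) |>
    dplyr::select(dplyr::all_of(c(
      "residue", "kind", "d_da", "sd_da", "segment_start", "segment_end",
      "conflict"
    ))) |>
    dplyr::arrange(
      is.na(.data$residue),
      .data$residue, .data$segment_start
    )
  neg <- res$kind == "resolved" & res$d_da < -3 * pmax(res$sd_da, 1e-12)
  if (any(neg)) {
    warning(
      sum(neg), " resolved residue(s) with deuterium below -3 SD ",
      "(flagged as conflict)",
      call. = FALSE
    )
    res$conflict[neg] <- TRUE
  }
  res
}

#' Per-residue titration fitting from fragment ladders across concentrations
#'
#' Resolves every ladder with [ladder_to_residues()], forms per-residue
#' protection series `delta = d_apo - d_bound(L)` expressed as percent of a
#' single amide's maximum uptake (`d_frac` Da), and fits each residue
#' resolved at >= 4 concentrations with [fit_langmuir()]. Segment-level
#' values are fitted too and labeled `segment`.
#'
#' @param ladders Named-by-concentration list, or list, of
#'   [fragment_ladder()] objects for the liganded states; ligand
#'   concentrations are taken from each ladder's `state` label (canonical
#'   `"L_<conc>"`) unless `conc_uM` is given.
#' @param apo_ladder A [fragment_ladder()] at ligand concentration 0.
#' @param conc_uM Optional numeric vector of ligand concentrations matching
#'   `ladders`.
#' @param d_frac D2O mole fraction (default 0.894).
#' @inheritParams fit_langmuir
#' @return Tibble, one row per residue or segment: `residue, kind,
#'   segment_start, segment_end, kd_uM, kd_se_uM, dmax_pct, cv_pct,
#'   accepted, reason, n_points`, plus a list-column `fit`.
#' @export
residue_titration <- function(ladders, apo_ladder, conc_uM = NULL,
                              d_frac = 0.894, min_dmax_pct = 20,
                              max_cv_pct = 20) {
  if (is.null(conc_uM)) {
    conc_uM <- vapply(ladders, function(l) {
      parse_state_label(l$state)$ligand_conc_uM
    }, numeric(1))
  }
  if (length(conc_uM) != length(ladders)) {
    stop("conc_uM must match ladders", call. = FALSE)
  }
  apo <- ladder_to_residues(apo_ladder)
  bound <- purrr::map2(ladders, conc_uM, function(l, cc) {
    dplyr::mutate(ladder_to_residues(l), conc_uM = cc)
  }) |> purrr::list_rbind()

  key <- function(d) {
    ifelse(d$kind == "segment",
      sprintf("seg_%d-%d", d$segment_start, d$segment_end),
      sprintf("res_%d", d$residue)
    )
  }
  apo$id <- key(apo)
  bound$id <- key(bound)
  fit_one <- function(id) {
    a <- apo[apo$id == id, ]
    b <- bound[bound$id == id, ]
    kind <- a$kind[1]
    n_amide <- if (kind == "segment") {
      length(observable_positions(apo_ladder$sequence)[
        observable_positions(apo_ladder$sequence) >= a$segment_start[1] &
          observable_positions(apo_ladder$sequence) <= a$segment_end[1]
      ])
    } else {
      1L
    }
    base <- tibble::tibble(
      residue = a$residue[1], kind = kind,
      segment_start = a$segment_start[1], segment_end = a$segment_end[1]
    )
    if (kind %in% c("proline", "excluded_nterm")) {
      # never fitted; emitted so downstream maps can annotate them
      return(dplyr::bind_cols(base, tibble::tibble(
        kd_uM = NA_real_, kd_se_uM = NA_real_, dmax_pct = NA_real_,
        cv_pct = NA_real_, accepted = FALSE, reason = kind,
        n_points = 0L, fit = list(NULL)
      )))
    }
    series <- tibble::tibble(
      conc_uM = b$conc_uM,
      delta_pct = 100 * (a$d_da[1] - b$d_da) / (n_amide * d_frac),
      sd_pct = 100 * sqrt(a$sd_da[1]^2 + b$sd_da^2) / (n_amide * d_frac)
    )
    if (nrow(series) < 4) {
      return(dplyr::bind_cols(base, tibble::tibble(
        kd_uM = NA_real_, kd_se_uM = NA_real_, dmax_pct = NA_real_,
        cv_pct = NA_real_, accepted = FALSE,
        reason = "resolved in < 4 concentrations", n_points = nrow(series),
        fit = list(NULL)
      )))
    }
    f <- fit_langmuir(series,
      min_dmax_pct = min_dmax_pct, max_cv_pct = max_cv_pct,
      target_id = id
    )
    dplyr::bind_cols(base, tibble::tibble(
      kd_uM = f$kd_uM, kd_se_uM = f$kd_se_uM, dmax_pct = f$dmax_pct,
      cv_pct = f$cv_dmax_pct, accepted = isTRUE(f$accepted),
      reason = f$reason, n_points = f$n_points, fit = list(f)
    ))
  }
  purrr::map(unique(apo$id), fit_one) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$kind != "resolved", .data$residue, .data$segment_start)
}

#' Scrambling metric from a selectively labeled standard (P1-style)
#'
#' Compares each fragment's observed deuterium with two predictions: the
#' no-scrambling prediction (sum of the site-specific model deuterium over
#' the fragment) and the full-scrambling prediction (precursor deuterium
#' distributed proportionally to labile-hydrogen counts). The per-fragment
#' position between the two, averaged, is the percent scrambling.
#'
#' @param ladder A [fragment_ladder()] of the standard peptide.
#' @param site_d Per-residue model deuterium (Da) under no scrambling
#'   (length = precursor length; zeros where nothing is labeled).
#' @param precursor_d Precursor deuterium content (Da); default the sum of
#'   `site_d`.
#' @param labile Per-residue labile-hydrogen counts (default
#'   [labile_hydrogens()] of the ladder sequence).
#' @param threshold_pct Flag threshold in percent (default 10).
#' @return A list of class `scrambling_report`: `method = "p1"`,
#'   `scrambling_pct`, `flagged`, `threshold`, `per_fragment` tibble.
#' @export
scrambling_p1 <- function(ladder, site_d, precursor_d = sum(site_d),
                          labile = NULL, threshold_pct = 10) {
  stopifnot(inherits(ladder, "fragment_ladder"))
  n <- ladder$n
  if (length(site_d) != n) {
    stop("site_d must cover every residue of the precursor", call. = FALSE)
  }
  if (is.null(labile)) labile <- labile_hydrogens(ladder$sequence)
  ions <- ladder$ions
  frag_res <- function(type, k) {
    if (type == "c") seq_len(k) else seq(n - k + 1, n)
  }
  per <- purrr::pmap(
    list(ions$ion_type, ions$ion_index, ions$d_content),
    function(type, k, obs) {
      rs <- frag_res(type, k)
      p0 <- sum(site_d[rs])
      p100 <- precursor_d * sum(labile[rs]) / sum(labile)
      tibble::tibble(
        ion = paste0(type, k), observed = obs,
        pred_none = p0, pred_full = p100,
        scrambling_pct = if (abs(p100 - p0) < 1e-12) {
          NA_real_
        } else {
          100 * (obs - p0) / (p100 - p0)
        }
      )
    }
  ) |> purrr::list_rbind()
  if (all(is.na(per$scrambling_pct))) {
    stop(
      "scrambling undefined: no fragment separates the no- and ",
      "full-scrambling predictions",
      call. = FALSE
    )
  }
  pct <- mean(per$scrambling_pct, na.rm = TRUE)
  structure(
    list(
      method = "p1", scrambling_pct = pct,
      flagged = pct > threshold_pct, threshold = threshold_pct,
      per_fragment = per
    ),
    class = "scrambling_report"
  )
}

#' Ammonia-loss scrambling check
#'
#' Compares the deuterium content of a charge-reduced species with that of
#' its ammonia-loss counterpart; a deuterium drop coincident with ammonia
#' loss indicates scrambling onto the lost NH3.
#'
#' @param d_rs Deuterium content of the charge-reduced species (Da).
#' @param d_rs_nh3 Deuterium content of the ammonia-loss species (Da).
#' @param pooled_sd Pooled SD of the two measurements (Da).
#' @param threshold_da Flag threshold (default 0.1 Da); the effective
#'   threshold is `max(threshold_da, 3 * pooled_sd)`.
#' @return A list of class `scrambling_report`: `method = "ammonia_loss"`,
#'   `d_difference_da`, `flagged`, `threshold`.
#' @examples
#' ammonia_loss_check(3.50, 3.48, 0.02) # not flagged
#' @export
ammonia_loss_check <- function(d_rs, d_rs_nh3, pooled_sd = 0,
                               threshold_da = 0.1) {
  if (d_rs < 0 || d_rs_nh3 < 0 || pooled_sd < 0) {
    stop("deuterium contents and SD must be non-negative", call. = FALSE)
  }
  diff_da <- d_rs - d_rs_nh3
  thr <- max(threshold_da, 3 * pooled_sd)
  structure(
    list(
      method = "ammonia_loss", d_difference_da = diff_da,
      flagged = diff_da > thr, threshold = thr
    ),
    class = "scrambling_report"
  )
}

#' @export
print.scrambling_report <- function(x, ...) {
  if (x$method == "p1") {
    cat(sprintf(
      "<scrambling_report> P1 method: %.1f%% scrambling (threshold %.0f%%) — %s\n",
      x$scrambling_pct, x$threshold, if (x$flagged) "FLAGGED" else "pass"
    ))
  } else {
    cat(sprintf(
      "<scrambling_report> ammonia loss: dD = %.3f Da (threshold %.3f) — %s\n",
      x$d_difference_da, x$threshold, if (x$flagged) "FLAGGED" else "pass"
    ))
  }
  invisible(x)
}

#' Read a fragment-ion centroid table
#'
#' Schema: `sequence,start,end,state,exposure_min,replicate,ion_type,
#' ion_index,charge,centroid_mz_undeut,centroid_mz_deut`.
#'
#' @param path CSV path.
#' @return Tibble with `d_content` added per ion.
#' @export
read_fragment_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tibble::as_tibble(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  )
  req <- c(
    "sequence", "state", "ion_type", "ion_index", "charge",
    "centroid_mz_undeut", "centroid_mz_deut"
  )
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  dplyr::mutate(raw,
    d_content = .data$charge * (.data$centroid_mz_deut - .data$centroid_mz_undeut)
  )
}

#' Write residue-level results CSV
#'
#' Schema: `residue,kind,d_da,sd_da,kd_uM,kd_se_uM,dmax_pct,cv_pct,accepted`
#' (columns present in `res` are written), suitable for downstream
#' structure-mapping tools.
#'
#' @param res Residue results tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_residue_results <- function(res, path) {
  cols <- c(
    "residue", "kind", "segment_start", "segment_end", "d_da", "sd_da",
    "kd_uM", "kd_se_uM", "dmax_pct", "cv_pct", "accepted", "reason"
  )
  readr::write_csv(res[intersect(cols, names(res))], path, progress = FALSE)
  invisible(path)
}
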
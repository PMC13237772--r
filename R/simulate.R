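# Forward simulator of EX2 hydrogen-deuterium exchange under ligand
# occupancy: the ground-truth generator that makes every analysis stage
# testable at desk scale and quantifies the method's assumptions.

#' Fractional ligand occupancy from the single-site isotherm
#'
#' @param ligand_conc_uM Free ligand concentration, micromolar.
#' @param kd_uM Dissociation constant, micromolar.
#' @return Occupancy `L / (K_D + L)` in \[0, 1\].
#' @examples
#' occupancy(4.8, 4.8) # 0.5 at L = K_D
#' @export
occupancy <- function(ligand_conc_uM, kd_uM) {
  if (any(ligand_conc_uM < 0) || any(kd_uM <= 0)) {
    stop("concentrations must be >= 0 and kd > 0", call. = FALSE)
  }
  ligand_conc_uM / (kd_uM + ligand_conc_uM)
}

#' Exact free-ligand concentration under 1:1 depletion
#'
#' Solves the quadratic equilibrium for the free ligand when a protein at
#' `protein_conc_uM` binds a ligand dosed at `total_ligand_uM`, quantifying
#' how good the no-depletion approximation (free = total) is at each
#' titration point.
#'
#' @param protein_conc_uM Total protein concentration, micromolar.
#' @param total_ligand_uM Total ligand concentration, micromolar.
#' @param kd_uM True dissociation constant, micromolar.
#' @return A list: `free_ligand_uM` and `depletion_fraction`
#'   (`1 - free/total`).
#' @examples
#' ligand_depletion(1, 0.95, 4.8) # ~15% depletion
#' @export
ligand_depletion <- function(protein_conc_uM, total_ligand_uM, kd_uM) {
  if (protein_conc_uM <= 0 || any(total_ligand_uM <= 0) || kd_uM <= 0) {
    stop("all concentrations must be > 0", call. = FALSE)
  }
  b <- kd_uM + protein_conc_uM - total_ligand_uM
  free <- (-b + sqrt(b^2 + 4 * kd_uM * total_ligand_uM)) / 2
  list(
    free_ligand_uM = free,
    depletion_fraction = 1 - free / total_ligand_uM
  )
}

#' Build per-amide exchange-site models for a construct
#'
#' Each observable backbone amide gets an intrinsic exchange rate and a
#' protection factor for the free and the ligand-bound state; binding-site
#' residues are additionally protected when bound. Prolines and the two
#' N-terminal residues of the construct are non-observable.
#'
#' @param construct A [protein_construct()].
#' @param binding_site Construct-local residue numbers protected by the
#'   ligand.
#' @param k_int_per_min Intrinsic rates: a scalar, a per-residue vector, or
#'   `NULL` to sample log-normally (median 10 per min, sigma_log10 = 1).
#' @param p_free Protection factor in the free state (scalar or vector,
#'   default 10).
#' @param p_bound_ratio Extra protection at binding-site residues when
#'   bound: `p_bound = p_free * p_bound_ratio` there, `p_free` elsewhere
#'   (default 50).
#' @param seed Seed for rate sampling when `k_int_per_min` is `NULL`.
#' @return Tibble `residue, k_int_per_min, p_free, p_bound, observable`.
#' @export
exchange_site_models <- function(construct, binding_site = integer(0),
                                 k_int_per_min = NULL, p_free = 10,
                                 p_bound_ratio = 50, seed = 1L) {
  n <- construct$length
  aa <- strsplit(construct$sequence, "")[[1]]
  if (is.null(k_int_per_min)) {
    set.seed(seed)
    k_int_per_min <- 10^(log10(10) + rnorm(n, 0, 1))
  } else if (length(k_int_per_min) == 1) {
    k_int_per_min <- rep(k_int_per_min, n)
  }
  p_free <- if (length(p_free) == 1) rep(p_free, n) else p_free
  stopifnot(length(k_int_per_min) == n, length(p_free) == n)
  if (any(p_free < 1)) stop("protection factors must be >= 1", call. = FALSE)
  p_bound <- p_free
  p_bound[binding_site] <- p_free[binding_site] * p_bound_ratio
  tibble::tibble(
    residue = seq_len(n),
    k_int_per_min = k_int_per_min,
    p_free = p_free,
    p_bound = p_bound,
    observable = seq_len(n) > 2 & aa != "P"
  )
}

#' Deuterium uptake of one amide under partial ligand occupancy
#'
#' Two interconversion regimes are implemented. In `fast_exchange`
#' (rapid conformational pre-equilibrium relative to labeling) the amide
#' exchanges with the occupancy-averaged rate
#' \deqn{k_{obs} = k_{int}(\theta/P_{bound} + (1-\theta)/P_{free}),}
#' so \eqn{D = d_{frac}(1 - e^{-k_{obs} t})} — uptake is *not* linear in
#' occupancy except at short exposures. In `slow_mixture` (bound and free
#' populations exchange independently over the labeling window)
#' \deqn{D = d_{frac}[\theta(1 - e^{-k_{int} t/P_{bound}}) +
#'   (1-\theta)(1 - e^{-k_{int} t/P_{free}})],}
#' which makes the protection exactly proportional to occupancy, hence
#' exactly Langmuir in the ligand concentration.
#'
#' @param k_int_per_min Intrinsic exchange rate (per minute).
#' @param p_free,p_bound Protection factors (>= 1) in the free and bound
#'   states.
#' @param theta Fractional occupancy in \[0, 1\].
#' @param t_min Exposure, minutes.
#' @param d_frac D2O mole fraction (default 0.894).
#' @param regime `"slow_mixture"` (default) or `"fast_exchange"`.
#' @return Expected uptake of the site, Da, in \[0, d_frac\].
#' @export
site_uptake <- function(k_int_per_min, p_free, p_bound, theta, t_min,
                        d_frac = 0.894,
                        regime = c("slow_mixture", "fast_exchange")) {
  regime <- match.arg(regime)
  if (any(theta < 0 | theta > 1)) stop("theta must lie in [0, 1]", call. = FALSE)
  if (any(t_min < 0)) stop("t_min must be >= 0", call. = FALSE)
  if (regime == "fast_exchange") {
    k_obs <- k_int_per_min * (theta / p_bound + (1 - theta) / p_free)
    d_frac * (1 - exp(-k_obs * t_min))
  } else {
    d_frac * (theta * (1 - exp(-k_int_per_min * t_min / p_bound)) +
      (1 - theta) * (1 - exp(-k_int_per_min * t_min / p_free)))
  }
}

#' Simulation protocol mirroring the standard titration design
#'
#' Defaults reproduce the reference experimental design: 1 uM protein, a
#' two-fold ligand series of nominal 1-128 uM (final in-labeling
#' concentrations x 57/60, top ~121.6 uM), a single 5 min exposure, final
#' D2O fraction 0.894, three replicates.
#'
#' @param kd_true_uM True dissociation constant (default 4.8).
#' @param protein_conc_uM Protein concentration (default 1).
#' @param ligand_concs_uM Final in-labeling concentrations (default
#'   `final_ligand_conc(2^(0:7))`).
#' @param exposures_min Labeling times (default 5).
#' @param d_frac D2O mole fraction (default 0.894).
#' @param n_replicates Replicates per condition (default 3).
#' @param noise_sd_da Gaussian replicate noise on peptide uptake, Da
#'   (default 0.05).
#' @param regime Exchange regime (see [site_uptake()]).
#' @param seed RNG seed (default 1).
#' @param deplete Apply exact 1:1 ligand depletion to the occupancies
#'   (default FALSE: the no-depletion idealization).
#' @return A list of class `sim_protocol`.
#' @export
sim_protocol <- function(kd_true_uM = 4.8, protein_conc_uM = 1,
                         ligand_concs_uM = final_ligand_conc(2^(0:7)),
                         exposures_min = 5, d_frac = 0.894,
                         n_replicates = 3, noise_sd_da = 0.05,
                         regime = c("slow_mixture", "fast_exchange"),
                         seed = 1L, deplete = FALSE) {
  regime <- match.arg(regime)
  stopifnot(
    kd_true_uM > 0, protein_conc_uM > 0,
    all(ligand_concs_uM > 0), !anyDuplicated(ligand_concs_uM),
    all(exposures_min > 0), !anyDuplicated(exposures_min),
    d_frac > 0, d_frac <= 1, n_replicates >= 1, noise_sd_da >= 0
  )
  structure(
    list(
      kd_true_uM = kd_true_uM, protein_conc_uM = protein_conc_uM,
      ligand_concs_uM = ligand_concs_uM, exposures_min = exposures_min,
      d_frac = d_frac, n_replicates = n_replicates,
      noise_sd_da = noise_sd_da, regime = regime, seed = as.integer(seed),
      deplete = deplete
    ),
    class = "sim_protocol"
  )
}

# Expected per-site uptake matrix (sites x 1) at occupancy theta, time t.
sites_uptake_vec <- function(sites, theta, t_min, d_frac, regime) {
  ifelse(
    sites$observable,
    site_uptake(sites$k_int_per_min, sites$p_free, sites$p_bound,
      theta, t_min,
      d_frac = d_frac, regime = regime
    ),
    0
  )
}

#' Simulate a full titration experiment
#'
#' Generates a peptide-level uptake table (canonical schema, apo state plus
#' one liganded state per concentration), per the protocol's exchange
#' regime, with Gaussian replicate noise; deterministic for a fixed seed.
#' Peptide uptake is the sum of the expected uptake over the peptide's
#' observable amides (position 1-2 and proline exclusions applied at the
#' peptide level, as in a real bottom-up experiment).
#'
#' @param construct A [protein_construct()].
#' @param peptides Peptide table (see [peptide_table()]); validated against
#'   the construct.
#' @param sites Site models from [exchange_site_models()], one row per
#'   construct residue.
#' @param protocol A [sim_protocol()].
#' @return A list: `uptake` (tibble in the canonical uptake schema with
#'   `ligand_conc_uM` and `n_exchangeable`), `truth` (per-residue sidecar
#'   `residue, k_int_per_min, p_free, p_bound, kd_true_uM`), `protocol`.
#' @export
simulate_titration <- function(construct, peptides, sites, protocol) {
  stopifnot(inherits(protocol, "sim_protocol"))
  peptides <- peptide_table(peptides, construct)
  if (nrow(sites) != construct$length) {
    stop("site models must cover every construct residue", call. = FALSE)
  }
  concs <- c(0, protocol$ligand_concs_uM)
  thetas <- vapply(concs, function(L) {
    if (L == 0) {
      0
    } else if (protocol$deplete) {
      occupancy(
        ligand_depletion(protocol$protein_conc_uM, L, protocol$kd_true_uM)$free_ligand_uM,
        protocol$kd_true_uM
      )
    } else {
      occupancy(L, protocol$kd_true_uM)
    }
  }, numeric(1))

  set.seed(protocol$seed)
  grid <- tidyr::expand_grid(
    pi = seq_len(nrow(peptides)),
    ci = seq_along(concs),
    exposure_min = protocol$exposures_min,
    replicate = seq_len(protocol$n_replicates)
  )
  rows <- purrr::pmap(grid, function(pi, ci, exposure_min, replicate) {
    p <- peptides[pi, ]
    site_pos <- p$start + observable_positions(p$sequence) - 1
    d <- sites_uptake_vec(
      sites[site_pos, ], thetas[ci], exposure_min,
      protocol$d_frac, protocol$regime
    )
    tibble::tibble(
      protein = construct$name, sequence = p$sequence,
      start = p$start, end = p$end,
      ligand_conc_uM = concs[ci], exposure_min = exposure_min,
      replicate = replicate, charge = NA_integer_,
      uptake_da = sum(d), uptake_sd = NA_real_,
      n_exchangeable = p$n_exchangeable
    )
  }) |> purrr::list_rbind()
  rows$uptake_da <- rows$uptake_da +
    rnorm(nrow(rows), 0, protocol$noise_sd_da)
  rows$state <- ifelse(rows$ligand_conc_uM == 0, "apo",
    paste0("L_", format(rows$ligand_conc_uM, trim = TRUE))
  )
  rows <- dplyr::select(rows, dplyr::all_of(c(
    "protein", "sequence", "start", "end", "state", "exposure_min",
    "replicate", "charge", "uptake_da", "uptake_sd", "ligand_conc_uM",
    "n_exchangeable"
  )))
  truth <- dplyr::transmute(sites,
    residue = .data$residue, k_int_per_min = .data$k_int_per_min,
    p_free = .data$p_free, p_bound = .data$p_bound,
    kd_true_uM = protocol$kd_true_uM
  )
  list(uptake = rows, truth = truth, protocol = protocol)
}

#' Simulate a noise-free ECD fragment ladder for one peptide and state
#'
#' Per-site expected deuterium is accumulated into c- and z-ion deuterium
#' contents by partial sums (amide of peptide position j enters c_j; z_k
#' carries the C-terminal k positions), then expressed as centroid m/z
#' pairs so the ladder follows the same schema as measured data.
#'
#' @param peptide_sequence Peptide sequence.
#' @param site_d Per-peptide-position deuterium (Da), zeros at
#'   non-observable positions; e.g. built from [site_uptake()].
#' @param c_indices,z_indices Ion indices to emit (defaults: full series
#'   1..n-1).
#' @param charge Fragment charge used for the synthetic centroids
#'   (default 1).
#' @param state,exposure_min Labels carried into the ladder.
#' @return A [fragment_ladder()] with `precursor_d = sum(site_d)`.
#' @export
simulate_ladder <- function(peptide_sequence, site_d,
                            c_indices = NULL, z_indices = NULL,
                            charge = 1L, state = "apo", exposure_min = 5) {
  aa <- validate_sequence(peptide_sequence)
  n <- length(aa)
  if (length(site_d) != n) stop("site_d must have one value per residue", call. = FALSE)
  if (is.null(c_indices)) c_indices <- seq_len(n - 1)
  if (is.null(z_indices)) z_indices <- seq_len(n - 1)
  base_mz <- 500 # arbitrary synthetic undeuterated centroid
  mk <- function(type, idx) {
    if (length(idx) == 0) {
      return(NULL)
    }
    d <- vapply(idx, function(k) {
      rs <- if (type == "c") seq_len(k) else seq(n - k + 1, n)
      sum(site_d[rs])
    }, numeric(1))
    tibble::tibble(
      ion_type = type, ion_index = as.integer(idx), charge = as.integer(charge),
      centroid_mz_undeut = base_mz + idx,
      centroid_mz_deut = base_mz + idx + d / charge,
      sd = 0
    )
  }
  ions <- dplyr::bind_rows(mk("c", c_indices), mk("z", z_indices))
  fragment_ladder(ions, peptide_sequence,
    precursor_d = sum(site_d),
    state = state, exposure_min = exposure_min
  )
}

#' Redistribute deuterium as intramolecular scrambling would
#'
#' A fraction of the population's deuterium is redistributed over all
#' residues proportionally to their labile-hydrogen counts; the total is
#' conserved exactly. Fraction 0 is the identity; fraction 1 is full
#' scrambling.
#'
#' @param site_d Per-residue deuterium (Da) of the precursor.
#' @param fraction Scrambled population fraction in \[0, 1\].
#' @param labile Per-residue labile-hydrogen counts.
#' @return Redistributed per-residue deuterium, same total.
#' @export
scramble_operator <- function(site_d, fraction, labile) {
  if (fraction < 0 || fraction > 1) {
    stop("fraction must lie in [0, 1]", call. = FALSE)
  }
  if (length(labile) != length(site_d)) {
    stop("labile counts must match site_d", call. = FALSE)
  }
  total <- sum(site_d)
  (1 - fraction) * site_d + fraction * total * labile / sum(labile)
}
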
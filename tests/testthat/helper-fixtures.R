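# Shared fixtures, built in code.

# The standard 8-point two-fold titration design (final in-labeling
# concentrations, uM).
design_concs <- final_ligand_conc(2^(0:7))

# A 50-residue synthetic construct with a binding site at residues 21-30.
fix_construct <- function() {
  protein_construct("synthetic50", strrep("GASTLIVEKR", 5))
}

fix_sites <- function(seed = 7, binding_site = 21:30, p_bound_ratio = 50) {
  exchange_site_models(fix_construct(),
    binding_site = binding_site,
    p_bound_ratio = p_bound_ratio, seed = seed
  )
}

fix_peptides <- function() {
  construct <- fix_construct()
  starts <- seq(1, 41, by = 10)
  data.frame(
    start = starts, end = starts + 9,
    sequence = substring(construct$sequence, starts, starts + 9)
  )
}

fix_sim <- function(kd = 5, noise = 0, seed = 1, regime = "slow_mixture",
                    exposures = 5) {
  simulate_titration(
    fix_construct(), fix_peptides(), fix_sites(),
    sim_protocol(
      kd_true_uM = kd, noise_sd_da = noise, seed = seed,
      regime = regime, exposures_min = exposures
    )
  )
}

# A 16-mer with prolines at peptide positions 9 and 13 (observable amides:
# 3-8, 10-12, 14-16).
frag_seq <- "LEKQQSAWPFLKPVSL"

frag_site_d <- function(seed = 2) {
  n <- nchar(frag_seq)
  obs <- setdiff(3:n, c(9, 13))
  d <- numeric(n)
  set.seed(seed)
  d[obs] <- runif(length(obs), 0.1, 0.894)
  d
}

# Independent Welch t-test p-value from first principles (not stats::t.test).
oracle_welch_p <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * pt(-abs(t_stat), df)
}

# Brute-force 2-D grid search over (log KD, Dmax) for the Langmuir RSS.
oracle_grid_fit <- function(conc, y, kd_range = c(0.05, 500),
                            dmax_range = NULL, n_grid = 400) {
  if (is.null(dmax_range)) dmax_range <- c(max(y) * 0.3, max(y) * 2)
  kds <- exp(seq(log(kd_range[1]), log(kd_range[2]), length.out = n_grid))
  dmaxs <- seq(dmax_range[1], dmax_range[2], length.out = n_grid)
  rss <- outer(kds, dmaxs, function(kd, dm) {
    vapply(seq_along(kd), function(i) {
      sum((y - dm[i] * conc / (kd[i] + conc))^2)
    }, numeric(1))
  })
  best <- arrayInd(which.min(rss), dim(rss))
  list(
    kd = kds[best[1]], dmax = dmaxs[best[2]],
    kd_step = kds[min(best[1] + 1, n_grid)] / kds[best[1]],
    dmax_step = dmaxs[2] - dmaxs[1]
  )
}
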
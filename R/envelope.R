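# Isotope-envelope arithmetic: natural isotopic distributions by iterative
# convolution, Poisson-binomial deuterium incorporation, centroiding, and
# centroid-difference uptake. Envelopes are stick spectra (m/z, intensity).

#' Elemental composition of a peptide
#'
#' Sum of residue compositions plus one water.
#'
#' @param sequence One-letter amino-acid string.
#' @return Named integer vector with counts of C, H, N, O, S.
#' @examples
#' peptide_composition("GG") # C4 H8 N2 O3
#' @export
peptide_composition <- function(sequence) {
  aa <- validate_sequence(sequence)
  comp <- colSums(.residue_comp[aa, , drop = FALSE])
  comp["H"] <- comp["H"] + 2 # + H2O
  comp["O"] <- comp["O"] + 1
  stats::setNames(as.integer(comp), colnames(.residue_comp))
}

#' Construct an isotope envelope
#'
#' @param mz Numeric vector of m/z values, strictly increasing.
#' @param intensity Non-negative intensities, at least one positive.
#' @param charge Positive integer charge state.
#' @return Object of class `isotope_envelope`: a tibble with columns `mz`,
#'   `intensity` and attribute `charge`.
#' @export
isotope_envelope <- function(mz, intensity, charge) {
  if (length(mz) != length(intensity) || length(mz) == 0) {
    stop("mz and intensity must be equal-length and non-empty", call. = FALSE)
  }
  if (is.unsorted(mz, strictly = TRUE)) {
    stop("m/z values must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(intensity)) || any(intensity < 0) || all(intensity == 0)) {
    stop("intensities must be finite, non-negative, not all zero",
      call. = FALSE
    )
  }
  if (charge < 1 || charge != round(charge)) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  out <- tibble::tibble(mz = as.numeric(mz), intensity = as.numeric(intensity))
  attr(out, "charge") <- as.integer(charge)
  class(out) <- c("isotope_envelope", class(out))
  out
}

#' @export
print.isotope_envelope <- function(x, ...) {
  cat(
    "<isotope_envelope> charge ", attr(x, "charge"), ", ", nrow(x),
    " peaks, centroid ", round(centroid(x), 4), " m/z\n",
    sep = ""
  )
  invisible(x)
}

# Convolve two (mass-shift, probability) distributions given as data frames
# with columns dm (Da) and p, aggregating by nucleon number while tracking
# the intensity-weighted mean mass per bin.
convolve_dist <- function(a, b) {
  dm <- outer(a$dm, b$dm, `+`)
  p <- outer(a$p, b$p)
  key <- round(dm)
  tot <- tapply(as.vector(p), as.vector(key), sum)
  wm <- tapply(as.vector(p * dm), as.vector(key), sum) / tot
  ord <- order(as.numeric(names(tot)))
  data.frame(dm = as.numeric(wm[ord]), p = as.numeric(tot[ord]))
}

# Truncate a distribution to cumulative probability >= keep, then renormalize.
truncate_dist <- function(d, keep = 0.9999) {
  ord <- order(d$p, decreasing = TRUE)
  cum <- cumsum(d$p[ord])
  k <- which(cum >= keep)[1]
  if (is.na(k)) k <- length(ord)
  sel <- sort(ord[seq_len(k)])
  d <- d[sel, , drop = FALSE]
  d$p <- d$p / sum(d$p)
  d
}

#' Natural isotope envelope of an elemental composition
#'
#' Computed by iterative convolution of per-element isotope vectors (fixed
#' internal mass/abundance table), aggregated by nucleon number with
#' intensity-weighted mean masses, truncated at 0.9999 cumulative intensity
#' and renormalized to total intensity 1.
#'
#' @param composition Named counts of C, H, N, O, S atoms (see
#'   [peptide_composition()]).
#' @param charge Positive integer charge; m/z uses proton charge carriers.
#' @param truncate Cumulative-intensity truncation threshold (default
#'   0.9999; set to 1 to keep every peak).
#' @return An [isotope_envelope()].
#' @examples
#' natural_envelope(c(C = 6, H = 12, N = 2, O = 2, S = 0), charge = 1)
#' @export
natural_envelope <- function(composition, charge = 1L, truncate = 0.9999) {
  comp <- composition[intersect(names(.isotopes), names(composition))]
  comp <- comp[!is.na(comp) & comp > 0]
  if (length(comp) == 0 || sum(comp) == 0) {
    stop("composition has no atoms", call. = FALSE)
  }
  mono <- 0
  dist <- data.frame(dm = 0, p = 1)
  for (el in names(comp)) {
    iso <- .isotopes[[el]]
    mono <- mono + comp[[el]] * iso$mass[1]
    base <- data.frame(dm = iso$mass - iso$mass[1], p = iso$abund)
    # binary-exponentiation power of the element distribution
    n <- comp[[el]]
    pow <- base
    acc <- NULL
    while (n > 0) {
      if (n %% 2 == 1) acc <- if (is.null(acc)) pow else convolve_dist(acc, pow)
      n <- n %/% 2
      if (n > 0) pow <- convolve_dist(pow, pow)
      if (!is.null(acc)) acc <- truncate_dist(acc, keep = 1 - 1e-12)
      pow <- truncate_dist(pow, keep = 1 - 1e-12)
    }
    dist <- convolve_dist(dist, acc)
    dist <- truncate_dist(dist, keep = 1 - 1e-12)
  }
  dist <- truncate_dist(dist, keep = truncate)
  mz <- (mono + dist$dm + charge * hdx_constants$mass_proton) / charge
  isotope_envelope(mz, dist$p, charge)
}

# Poisson-binomial distribution of deuterium count over independent sites.
# Returns data.frame(k, p), k = 0..n.
poisson_binomial <- function(probs) {
  p <- c(1, numeric(length(probs)))
  for (q in probs) {
    p <- c(p * (1 - q), 0) + c(0, p * q)
  }
  data.frame(k = seq_along(p) - 1, p = p)
}

#' Incorporate deuterium into an envelope
#'
#' Convolves the input envelope with the Poisson-binomial distribution of
#' the deuterium count over independent exchange sites; each deuterium adds
#' the H-to-D mass difference (1.006277 Da) divided by the charge. A
#' back-exchange factor < 1 scales every site probability.
#'
#' @param envelope An [isotope_envelope()].
#' @param site_probs Per-site deuteration probabilities in \[0, 1\].
#' @param back_exchange_factor Multiplicative back-exchange retention in
#'   (0, 1\]; default 1 (no correction).
#' @return A new [isotope_envelope()] with total intensity preserved.
#' @export
incorporate_deuterium <- function(envelope, site_probs,
                                  back_exchange_factor = 1) {
  if (any(site_probs < 0 | site_probs > 1)) {
    stop("site probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (back_exchange_factor <= 0 || back_exchange_factor > 1) {
    stop("back_exchange_factor must lie in (0, 1]", call. = FALSE)
  }
  probs <- site_probs * back_exchange_factor
  if (length(probs) == 0) {
    return(envelope)
  }
  charge <- attr(envelope, "charge")
  pb <- poisson_binomial(probs)
  pb <- pb[pb$p > 0, , drop = FALSE]
  mz <- as.vector(outer(
    envelope$mz, pb$k * hdx_constants$mass_h_to_d / charge, `+`
  ))
  int <- as.vector(outer(envelope$intensity, pb$p))
  key <- round(mz, 9)
  tot <- tapply(int, key, sum)
  wm <- tapply(int * mz, key, sum) / tot
  ord <- order(as.numeric(wm))
  isotope_envelope(as.numeric(wm[ord]), as.numeric(tot[ord]), charge)
}

#' Intensity-weighted centroid of an envelope
#'
#' @param envelope An [isotope_envelope()], or any data frame with `mz` and
#'   `intensity` columns.
#' @return Centroid m/z.
#' @export
centroid <- function(envelope) {
  if (sum(envelope$intensity) <= 0) {
    stop("total intensity must be positive", call. = FALSE)
  }
  sum(envelope$mz * envelope$intensity) / sum(envelope$intensity)
}

#' Deuterium uptake from deuterated and undeuterated centroids
#'
#' @param centroid_deut,centroid_undeut Centroid m/z of the deuterated and
#'   undeuterated species.
#' @param charge Positive integer charge state.
#' @return Uptake in Da: `charge * (centroid_deut - centroid_undeut)`.
#'   Negative values are preserved (systematic errors stay visible); a
#'   warning flags them.
#' @examples
#' uptake_from_centroids(626.30, 624.40, 3) # 5.70 Da
#' @export
uptake_from_centroids <- function(centroid_deut, centroid_undeut, charge) {
  if (any(charge < 1)) stop("charge must be >= 1", call. = FALSE)
  up <- charge * (centroid_deut - centroid_undeut)
  if (any(up < 0)) {
    warning("negative uptake value(s) preserved, not clipped", call. = FALSE)
  }
  up
}

#' Read a peak-list file (one envelope)
#'
#' Two-column whitespace- or comma-delimited text (m/z, intensity), one
#' envelope per file, with the charge in a `# charge=N` header line.
#'
#' @param path File path.
#' @return An [isotope_envelope()].
#' @export
read_peak_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  m <- regmatches(hdr, regexpr("charge\\s*=\\s*[0-9]+", hdr))
  if (length(m) == 0) stop("no '# charge=N' header in ", path, call. = FALSE)
  charge <- as.integer(sub(".*=\\s*", "", m[[1]]))
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(trimws(body), "[,\\s]+")
  mz <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
  int <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  ord <- order(mz)
  isotope_envelope(mz[ord], int[ord], charge)
}

#' Write a peak-list file
#'
#' @param envelope An [isotope_envelope()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_list <- function(envelope, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# charge=%d", attr(envelope, "charge")), con)
  writeLines(sprintf("%.9f,%.9g", envelope$mz, envelope$intensity), con)
  invisible(path)
}

#' @rdname centroid
#' @param object,x An `isotope_envelope`.
#' @param ... Unused.
#' @method autoplot isotope_envelope
#' @export
autoplot.isotope_envelope <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0)) +
    ggplot2::geom_vline(
      xintercept = centroid(object), linetype = "dashed",
      colour = "firebrick"
    ) +
    ggplot2::labs(x = "m/z", y = "relative intensity") +
    ggplot2::theme_minimal()
}
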
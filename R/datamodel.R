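# Domain types and IO for peptide-level uptake tables.
#
# Coordinates are 1-based, inclusive start/end, construct-local; an explicit
# numbering offset maps construct residue 1 to its full-length number.
# Canonical state labels are "apo" and "L_<conc_uM>".

#' Define a protein construct
#'
#' @param name Construct name.
#' @param sequence One-letter amino-acid sequence (20 canonical residues).
#' @param numbering_offset Full-length residue number of construct residue 1
#'   minus one; construct-local residue `i` corresponds to full-length
#'   `i + numbering_offset`. Default 0.
#' @return A list of class `protein_construct` with fields `name`, `sequence`,
#'   `numbering_offset` and `length`.
#' @examples
#' protein_construct("toy", "GCNSTARWAY")
#' @export
protein_construct <- function(name, sequence, numbering_offset = 0L) {
  aa <- validate_sequence(sequence)
  if (numbering_offset < 0) stop("`numbering_offset` must be >= 0", call. = FALSE)
  structure(
    list(
      name = name, sequence = paste(aa, collapse = ""),
      numbering_offset = as.integer(numbering_offset), length = length(aa)
    ),
    class = "protein_construct"
  )
}

#' @export
print.protein_construct <- function(x, ...) {
  cat(
    "<protein_construct> ", x$name, ": ", x$length, " aa, offset ",
    x$numbering_offset, "\n",
    sep = ""
  )
  invisible(x)
}

#' Maximum number of exchange-observable backbone amides of a peptide
#'
#' Uses the N - 2 - P convention: the first residue carries no measured
#' backbone amide, the second is discounted for rapid back-exchange, and
#' prolines from position 3 onward have no backbone amide hydrogen at all.
#'
#' @param sequence One-letter peptide sequence (length >= 2), or a character
#'   vector of such sequences.
#' @param n_term_excluded Number of N-terminal residues excluded (default 2;
#'   the field convention).
#' @return Integer vector of observable-amide counts, never negative.
#' @examples
#' max_exchangeable_amides("LEKQQSAWPFLKPVSL") # 12: P at positions 9 and 13
#' @export
max_exchangeable_amides <- function(sequence, n_term_excluded = 2L) {
  vapply(sequence, function(s) {
    aa <- validate_sequence(s)
    n <- length(aa)
    if (n < 2) stop("peptide must have length >= 2", call. = FALSE)
    obs <- observable_positions(s, n_term_excluded)
    length(obs)
  }, integer(1), USE.NAMES = FALSE)
}

# Peptide positions (1-based within the peptide) carrying an observable
# backbone amide.
observable_positions <- function(sequence, n_term_excluded = 2L) {
  aa <- validate_sequence(sequence)
  n <- length(aa)
  pos <- seq_len(n)
  pos[pos > n_term_excluded & aa != "P"]
}

#' Build a validated peptide table
#'
#' @param peptides Data frame with columns `sequence`, `start`, `end`
#'   (construct-local, 1-based inclusive); other columns are preserved.
#' @param construct Optional [protein_construct()]; when given, each peptide
#'   sequence is checked against the construct slice.
#' @return Tibble with `n_exchangeable` added (see
#'   [max_exchangeable_amides()]).
#' @export
peptide_table <- function(peptides, construct = NULL) {
  peptides <- tibble::as_tibble(peptides)
  req <- c("sequence", "start", "end")
  miss <- setdiff(req, names(peptides))
  if (length(miss) > 0) {
    stop("peptide table lacks column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  bad <- which(peptides$end - peptides$start + 1 != nchar(peptides$sequence))
  if (length(bad) > 0) {
    stop(
      "peptide row(s) ", paste(head(bad, 5), collapse = ", "),
      ": end - start + 1 does not match sequence length",
      call. = FALSE
    )
  }
  if (!is.null(construct)) {
    slice <- substring(
      construct$sequence, peptides$start,
      peptides$end
    )
    bad <- which(toupper(peptides$sequence) != slice)
    if (length(bad) > 0) {
      stop(
        "peptide row(s) ", paste(head(bad, 5), collapse = ", "),
        " do not match the construct sequence",
        call. = FALSE
      )
    }
  }
  dplyr::mutate(peptides, n_exchangeable = max_exchangeable_amides(.data$sequence))
}

#' Parse state labels into kind and ligand concentration
#'
#' Canonical labels are `"apo"` (ligand concentration 0) and `"L_<conc>"`
#' with `<conc>` the final in-labeling ligand concentration in micromolar.
#' Vendor dialects are accommodated by `state_map`, an explicit named
#' character vector mapping observed labels to canonical ones.
#'
#' @param state Character vector of state labels.
#' @param state_map Optional named character vector, e.g.
#'   `c("Compound-8uM" = "L_8")`.
#' @return Tibble with columns `state` (canonical) and `ligand_conc_uM`.
#' @export
parse_state_label <- function(state, state_map = NULL) {
  lab <- as.character(state)
  if (!is.null(state_map)) {
    hit <- lab %in% names(state_map)
    lab[hit] <- unname(state_map[lab[hit]])
  }
  conc <- rep(NA_real_, length(lab))
  conc[tolower(lab) == "apo"] <- 0
  is_l <- grepl("^L_", lab)
  conc[is_l] <- suppressWarnings(as.numeric(sub("^L_", "", lab[is_l])))
  if (anyNA(conc)) {
    bad <- which(is.na(conc))
    stop(
      "unparseable state label(s) at position(s) ",
      paste(head(bad, 5), collapse = ", "), ": ",
      paste(unique(lab[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  tibble::tibble(
    state = ifelse(conc == 0, "apo", paste0("L_", format(conc, trim = TRUE))),
    ligand_conc_uM = conc
  )
}

#' Convert nominal pre-dilution ligand concentrations to final in-labeling
#' concentrations
#'
#' The labeling reaction dilutes the sample into deuterated buffer; with the
#' standard 3 uL sample + 57 uL buffer scheme the ligand prepared in the
#' buffer is diluted by 57/60 on protein addition (128 uM nominal becomes
#' 121.6 uM final; the top of the titration is ~120 uM).
#'
#' @param nominal_uM Nominal concentration(s), micromolar.
#' @param sample_uL,buffer_uL Mixed volumes (defaults 3 and 57).
#' @return Final in-labeling concentration(s), micromolar.
#' @export
final_ligand_conc <- function(nominal_uM, sample_uL = 3, buffer_uL = 57) {
  nominal_uM * buffer_uL / (sample_uL + buffer_uL)
}

# Canonical uptake-table columns.
.uptake_cols <- c(
  "protein", "sequence", "start", "end", "state", "exposure_min",
  "replicate", "charge", "uptake_da", "uptake_sd"
)

#' Read a peptide-level deuterium-uptake table
#'
#' The canonical schema is a CSV with header
#' `protein,sequence,start,end,state,exposure_min,replicate,charge,uptake_da,uptake_sd`.
#' Vendor exports with different column names (HDExaminer-style tables and
#' the like) are ingested by supplying `column_map`; state-label dialects by
#' `state_map` (see [parse_state_label()]).
#'
#' @param path CSV file path.
#' @param column_map Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g. `c(uptake_da = "Uptake")`.
#' @param state_map Optional state-label mapping.
#' @return Tibble of uptake records, one row per peptide x state x exposure x
#'   replicate, with `ligand_conc_uM` and `n_exchangeable` derived. Peptides
#'   are validated (start/end vs sequence length).
#' @export
read_uptake_table <- function(path, column_map = NULL, state_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tibble::as_tibble(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  )
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw)) {
        stop("mapped column '", src, "' not present in ", path, call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  mandatory <- setdiff(.uptake_cols, c("protein", "charge", "uptake_sd"))
  miss <- setdiff(mandatory, names(raw))
  if (length(miss) > 0) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"protein" %in% names(raw)) raw$protein <- NA_character_
  if (!"charge" %in% names(raw)) raw$charge <- NA_integer_
  if (!"uptake_sd" %in% names(raw)) raw$uptake_sd <- NA_real_
  st <- parse_state_label(raw$state, state_map)
  out <- raw |>
    dplyr::mutate(
      state = st$state, ligand_conc_uM = st$ligand_conc_uM,
      start = as.integer(.data$start), end = as.integer(.data$end),
      replicate = as.integer(.data$replicate)
    ) |>
    dplyr::select(dplyr::all_of(c(.uptake_cols, "ligand_conc_uM")))
  bad <- which(out$end - out$start + 1 != nchar(out$sequence))
  if (length(bad) > 0) {
    stop(
      "row(s) ", paste(head(bad, 5), collapse = ", "),
      ": end - start + 1 does not match sequence length",
      call. = FALSE
    )
  }
  if (any(out$exposure_min < 0)) stop("negative exposure_min", call. = FALSE)
  if (any(out$replicate < 1)) stop("replicate must be >= 1", call. = FALSE)
  dplyr::mutate(out, n_exchangeable = max_exchangeable_amides(.data$sequence))
}

#' Write an uptake table in the canonical CSV schema
#'
#' @param uptake Tibble as produced by [read_uptake_table()] or
#'   [simulate_titration()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_uptake_table <- function(uptake, path) {
  cols <- intersect(.uptake_cols, names(uptake))
  readr::write_csv(uptake[cols], path, progress = FALSE)
  invisible(path)
}

#' Peptide-map summary statistics
#'
#' Coverage is the percentage of construct residues covered by at least one
#' peptide; redundancy is the summed peptide length divided by the construct
#' length (so redundancy 8.7 means each residue is covered 8.7 times on
#' average).
#'
#' @param peptides Data frame with `start`, `end` (construct-local, 1-based).
#' @param protein_length Construct length in residues.
#' @return One-row tibble `n_peptides, coverage_pct, redundancy,
#'   mean_peptide_length`.
#' @examples
#' compute_coverage_stats(data.frame(start = c(1, 6), end = c(10, 15)), 20)
#' @export
compute_coverage_stats <- function(peptides, protein_length) {
  peptides <- tibble::as_tibble(peptides)
  if (nrow(peptides) == 0) stop("empty peptide collection", call. = FALSE)
  if (any(peptides$start < 1) || any(peptides$end > protein_length) ||
    any(peptides$end < peptides$start)) {
    stop("peptides must lie within [1, protein_length]", call. = FALSE)
  }
  covered <- logical(protein_length)
  for (i in seq_len(nrow(peptides))) {
    covered[peptides$start[i]:peptides$end[i]] <- TRUE
  }
  lens <- peptides$end - peptides$start + 1
  tibble::tibble(
    n_peptides = nrow(peptides),
    coverage_pct = 100 * sum(covered) / protein_length,
    redundancy = sum(lens) / protein_length,
    mean_peptide_length = mean(lens)
  )
}

#' Example dataset: peptide-level apparent K_D values for a bromodomain
#' titration
#'
#' Published peptide-level apparent dissociation constants for a small
#' molecule binding the *Plasmodium falciparum* GCN5 bromodomain, determined
#' by HDX-MS titration (eight ligand concentrations, 5 min labeling, n = 3).
#' Forty peptides with measurable protection; construct-local numbering.
#' Ships as plain CSV under `inst/extdata/`.
#'
#' @return Tibble `sequence, start, end, kd_uM, kd_se_uM` (40 rows).
#' @examples
#' head(example_peptide_kd())
#' @export
example_peptide_kd <- function() {
  path <- system.file("extdata", "pfgcn5_brd_peptide_kd.csv",
    package = "hdxkd", mustWork = TRUE
  )
  tibble::as_tibble(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  )
}
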
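# Independent reference implementations used as oracles, plus small
# fixture builders.  These deliberately avoid the package's own code paths.

# Welch (or pooled) two-sample t-test p-value from first principles.
ref_t_test_p <- function(x, y, var_equal = FALSE) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  tstat <- (mean(x) - mean(y)) / se
  2 * pt(-abs(tstat), df)
}

# Sliding-window sequon scan: N at i, X at i+1 (optionally not P),
# S/T/C at i+2.
ref_sequon_scan <- function(seq, exclude_proline = TRUE) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  hits <- integer()
  for (i in seq_len(max(n - 2, 0))) {
    if (res[i] != "N") next
    if (exclude_proline && res[i + 1] == "P") next
    if (res[i + 2] %in% c("S", "T", "C")) hits <- c(hits, i)
  }
  hits
}

# Character-by-character tryptic splitter (cleave after K/R not before P),
# zero missed cleavages.
ref_tryptic_split <- function(seq) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  peps <- character()
  cur <- ""
  for (i in seq_len(n)) {
    cur <- paste0(cur, res[i])
    cut <- res[i] %in% c("K", "R") && (i == n || res[i + 1] != "P")
    if (cut || i == n) {
      peps <- c(peps, cur)
      cur <- ""
    }
  }
  peps
}

# Exhaustive subset enumeration for glycan-shift matching.
ref_glycan_subsets <- function(masses, shift, tol) {
  n <- length(masses)
  out <- list()
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (abs(sum(masses[idx]) - shift) <= tol) out[[length(out) + 1]] <- idx
  }
  out
}

# Random canonical protein sequence (test-local RNG state).
random_protein <- function(n, letters_pool = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(letters_pool, n, replace = TRUE), collapse = "")
}

# A small hand-buildable intensity table.
make_intensity_rows <- function(protein_id, start, stop, slice, sample_id,
                                cohort, intensity, peptide_seq = NULL) {
  tibble::tibble(
    protein_id = protein_id,
    peptide_seq = if (is.null(peptide_seq)) sprintf("PEP%d_%d", start, stop) else peptide_seq,
    start = as.integer(start), stop = as.integer(stop),
    slice = slice, sample_id = sample_id, cohort = cohort,
    intensity = intensity
  )
}
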
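# In-silico tryptic digestion and mass arithmetic.
#
# Trypsin rule: cleave C-terminal to K or R, except when the next residue is
# proline.  Monoisotopic masses back m/z values; average masses back the
# gel-kDa arithmetic (SDS-PAGE estimates average mass).

# Monoisotopic residue masses (Da), canonical 20 amino acids.
.AA_MONO <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

# Average residue masses (Da).
.AA_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167,
  V = 99.1326, T = 101.1051, C = 103.1388, L = 113.1594,
  I = 113.1594, N = 114.1038, D = 115.0886, Q = 128.1307,
  K = 128.1741, E = 129.1155, M = 131.1926, H = 137.1411,
  F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

.MASS_WATER_MONO <- 18.0105646863
.MASS_WATER_AVG <- 18.01528
.MASS_PROTON <- 1.007276
# Carbamidomethylation of cysteine (fixed modification, off by default).
.MASS_CAM_MONO <- 57.021464
.MASS_CAM_AVG <- 57.0519

#' Peptide mass from sequence
#'
#' Sums residue masses plus one water.  Vectorized over sequences.
#'
#' @param sequence character vector of peptide sequences (canonical
#'   residues).
#' @param carbamidomethyl logical; add 57.0215 Da per cysteine for fixed
#'   carbamidomethylation (default `FALSE`).
#' @return tibble with columns `sequence`, `monoisotopic_Da`, `average_Da`.
#' @export
peptide_mass <- function(sequence, carbamidomethyl = FALSE) {
  sequence <- validate_sequence(sequence, what = "peptide")
  sum_masses <- function(seq, table, water, cam) {
    res <- strsplit(seq, "", fixed = TRUE)[[1]]
    m <- sum(table[res]) + water
    if (cam) m <- m + sum(res == "C") * if (identical(table, .AA_MONO)) .MASS_CAM_MONO else .MASS_CAM_AVG
    m
  }
  tibble::tibble(
    sequence = sequence,
    monoisotopic_Da = purrr::map_dbl(sequence, sum_masses, table = .AA_MONO,
                                     water = .MASS_WATER_MONO, cam = carbamidomethyl),
    average_Da = purrr::map_dbl(sequence, sum_masses, table = .AA_AVG,
                                water = .MASS_WATER_AVG, cam = carbamidomethyl)
  )
}

#' Mass-to-charge ratio of a protonated peptide ion
#'
#' `(M + z * 1.007276) / z` for a monoisotopic mass `M` (Da) and charge `z`.
#' Full precision is kept internally; round to 2 decimals for display.
#'
#' @param monoisotopic_Da numeric monoisotopic mass(es) in Da.
#' @param charge positive integer charge state(s).
#' @param digits optional number of decimals to round to (default: none).
#' @return numeric m/z in Thomson.
#' @export
mz <- function(monoisotopic_Da, charge, digits = NULL) {
  if (any(charge < 1) || any(charge != round(charge))) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  out <- (monoisotopic_Da + charge * .MASS_PROTON) / charge
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' m/z of a peptide sequence at a given charge
#'
#' Convenience wrapper composing [peptide_mass()] and [mz()].
#'
#' @inheritParams peptide_mass
#' @inheritParams mz
#' @return numeric m/z in Thomson.
#' @export
peptide_mz <- function(sequence, charge, digits = NULL, carbamidomethyl = FALSE) {
  mz(peptide_mass(sequence, carbamidomethyl)$monoisotopic_Da, charge, digits)
}

# Positions p such that trypsin cuts between p and p+1 (K/R not before P),
# plus the protein C-terminus.  Returns sorted integer vector.
tryptic_cut_sites <- function(sequence) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  kr <- which(res %in% c("K", "R"))
  kr <- kr[kr == n | res[pmin(kr + 1L, n)] != "P"]
  sort(unique(c(kr, n)))
}

.peptide_tbl <- function(protein_id, sequence, start, stop, missed, termini) {
  tibble::tibble(
    protein_id = protein_id, sequence = sequence,
    start = as.integer(start), stop = as.integer(stop),
    missed_cleavages = as.integer(missed), termini = termini
  )
}

.add_masses <- function(peptides, carbamidomethyl = FALSE) {
  if (nrow(peptides) == 0) {
    peptides$monoisotopic_Da <- numeric()
    peptides$average_Da <- numeric()
    return(peptides)
  }
  m <- peptide_mass(peptides$sequence, carbamidomethyl)
  peptides$monoisotopic_Da <- m$monoisotopic_Da
  peptides$average_Da <- m$average_Da
  peptides
}

#' Fully tryptic in-silico digestion
#'
#' Cleaves each protein C-terminal to K/R (not before P) and enumerates all
#' fully tryptic peptides with up to `max_missed` missed cleavages,
#' optionally filtered to a monoisotopic detectability mass window.
#'
#' @param proteins protein record table.
#' @param max_missed maximum missed cleavages (default 2).
#' @param mass_range optional `c(min_Da, max_Da)` monoisotopic window, e.g.
#'   `c(700, 4000)` for a typical LC-MS/MS acquisition range.
#' @param carbamidomethyl logical, passed to [peptide_mass()].
#' @return peptide tibble with columns `protein_id`, `sequence`, `start`,
#'   `stop`, `missed_cleavages`, `termini`, `monoisotopic_Da`, `average_Da`,
#'   sorted by protein and start.
#' @export
digest_protein <- function(proteins, max_missed = 2, mass_range = NULL,
                           carbamidomethyl = FALSE) {
  stopifnot(max_missed >= 0)
  out <- purrr::map2_dfr(proteins$id, proteins$sequence, function(pid, seq) {
    cuts <- tryptic_cut_sites(seq)
    starts <- c(1L, utils::head(cuts, -1) + 1L)
    nb <- length(starts)
    rows <- purrr::map_dfr(0:min(max_missed, nb - 1), function(k) {
      i <- seq_len(nb - k)
      .peptide_tbl(pid, substring(seq, starts[i], cuts[i + k]),
                   starts[i], cuts[i + k], k, "fully_tryptic")
    })
    rows
  })
  out <- .add_masses(out, carbamidomethyl)
  if (!is.null(mass_range)) {
    out <- out[out$monoisotopic_Da >= mass_range[1] &
                 out$monoisotopic_Da <= mass_range[2], , drop = FALSE]
  }
  dplyr::arrange(out, .data$protein_id, .data$start, .data$stop)
}

#' Semi-tryptic peptides flanking annotated cleavage sites
#'
#' For a biological cleavage between residues p and p+1, trypsin digestion
#' of the cleaved protein yields one peptide starting at p+1 and running to
#' the next tryptic boundary (`semi_tryptic_N`: non-tryptic N-terminus) and
#' one ending at p from the previous tryptic boundary (`semi_tryptic_C`).
#' With `max_missed > 0` the products are extended over further tryptic
#' boundaries.  When a product coincides with a fully tryptic peptide it is
#' flagged `fully_tryptic`.  A site at the protein terminus yields an empty
#' product on that side (no error).
#'
#' @param proteins protein record table.
#' @param sites cleavage sites: a tibble with `protein_id`, `position`
#'   (and optionally `label`), or a bare numeric vector when `proteins` has
#'   a single row.
#' @param max_missed missed cleavages allowed beyond the site (default 0).
#' @param carbamidomethyl logical, passed to [peptide_mass()].
#' @return peptide tibble (as [digest_protein()]) with an extra
#'   `site_position` column.
#' @export
semi_tryptic_products <- function(proteins, sites, max_missed = 0,
                                  carbamidomethyl = FALSE) {
  if (is.numeric(sites)) {
    if (nrow(proteins) != 1) {
      stop("bare numeric sites need a single-protein table", call. = FALSE)
    }
    sites <- tibble::tibble(protein_id = proteins$id, position = as.integer(sites))
  }
  lens <- stats::setNames(proteins$length, proteins$id)
  seqs <- stats::setNames(proteins$sequence, proteins$id)
  bad <- sites$position < 1 | sites$position >= lens[sites$protein_id]
  if (any(is.na(bad)) || any(bad)) {
    stop("cleavage site position out of range (needs 1 <= p < length)", call. = FALSE)
  }
  out <- purrr::pmap_dfr(list(sites$protein_id, sites$position), function(pid, p) {
    seq <- seqs[[pid]]
    cuts <- tryptic_cut_sites(seq)
    rows <- list()
    # C-terminal product(s): start at p + 1, end at following tryptic cuts.
    nxt <- cuts[cuts >= p + 1L]
    for (k in seq_len(min(max_missed + 1L, length(nxt)))) {
      stop_at <- nxt[k]
      termini <- if ((p %in% cuts) || p == 0L) "fully_tryptic" else "semi_tryptic_N"
      rows[[length(rows) + 1L]] <- .peptide_tbl(
        pid, substring(seq, p + 1L, stop_at), p + 1L, stop_at, k - 1L, termini
      )
    }
    # N-terminal product(s): end at p, start after preceding tryptic cuts.
    prev <- cuts[cuts < p]
    prev_starts <- rev(c(1L, prev + 1L))
    for (k in seq_len(min(max_missed + 1L, length(prev_starts)))) {
      start_at <- prev_starts[k]
      termini <- if (p %in% cuts) "fully_tryptic" else "semi_tryptic_C"
      rows[[length(rows) + 1L]] <- .peptide_tbl(
        pid, substring(seq, start_at, p), start_at, p, k - 1L, termini
      )
    }
    res <- dplyr::bind_rows(rows)
    res$site_position <- as.integer(p)
    res
  })
  out <- .add_masses(out, carbamidomethyl)
  dplyr::arrange(out, .data$protein_id, .data$site_position, .data$start)
}

#' Fragment mass in kDa with glycan correction
#'
#' Average mass of a protein subsequence (gel arithmetic) plus the mass of
#' any N-glycans whose sequon lies in the range and which survive the
#' deglycosylation treatment: Endo H removes `endoH_sensitive` glycans only,
#' PNGase F removes all, `none` keeps all.
#'
#' @param protein single-row protein record table (or list with `sequence`).
#' @param start,stop 1-based inclusive residue range (vectorized).
#' @param glycans optional tibble with `position`, `state`, `mass_kDa`
#'   (a `protein_id` column, if present, is filtered to this protein).
#' @param treatment one of `"none"`, `"endoH"`, `"pngaseF"`.
#' @return numeric mass(es) in kDa.
#' @export
fragment_mass <- function(protein, start, stop, glycans = NULL,
                          treatment = c("none", "endoH", "pngaseF")) {
  treatment <- match.arg(treatment)
  seq <- protein$sequence[[1]]
  len <- nchar(seq)
  if (any(start < 1 | stop > len | start > stop)) {
    stop("fragment range out of protein bounds", call. = FALSE)
  }
  if (!is.null(glycans) && "protein_id" %in% names(glycans) && "id" %in% names(protein)) {
    glycans <- glycans[glycans$protein_id == protein$id[[1]], , drop = FALSE]
  }
  purrr::map2_dbl(start, stop, function(s, e) {
    m <- peptide_mass(substr(seq, s, e))$average_Da / 1000
    if (!is.null(glycans) && nrow(glycans) > 0) {
      inside <- glycans$position >= s & glycans$position <= e
      survives <- switch(treatment,
        none = rep(TRUE, nrow(glycans)),
        endoH = glycans$state != "endoH_sensitive",
        pngaseF = rep(FALSE, nrow(glycans))
      )
      m <- m + sum(glycans$mass_kDa[inside & survives])
    }
    m
  })
}
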
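# Cleavage inference: region intensity ratios around candidate boundaries,
# change-point localization from gel-slice distributions, fragment
# enumeration with glycan-corrected masses, and band-mass algebra.

#' Describe a peptide region of an intensity table
#'
#' A region selects observations by gel-slice set and peptides by
#' coordinate predicates.  For example, the "ectodomain reference" of a
#' protein cleaved at residue b is
#' `region_spec(slices = "A", stop_lt = b)` and its membrane-bound
#' complement `region_spec(slices = LETTERS[2:10], stop_gt = b)`.
#'
#' @param slices character vector of slice labels, or `NULL` for all.
#' @param stop_lt,stop_gt exclusive bounds on peptide stop position.
#' @param start_ge,start_le inclusive bounds on peptide start position.
#' @param description optional free-text description.
#' @return an object of class `pcc_region_spec`.
#' @export
region_spec <- function(slices = NULL, stop_lt = NULL, stop_gt = NULL,
                        start_ge = NULL, start_le = NULL, description = NULL) {
  if (is.null(description)) {
    parts <- c(
      if (!is.null(slices)) paste0("slices {", paste(slices, collapse = ","), "}"),
      if (!is.null(stop_lt)) paste0("stop<", stop_lt),
      if (!is.null(stop_gt)) paste0("stop>", stop_gt),
      if (!is.null(start_ge)) paste0("start>=", start_ge),
      if (!is.null(start_le)) paste0("start<=", start_le)
    )
    description <- if (length(parts) > 0) paste(parts, collapse = " & ") else "all peptides"
  }
  structure(list(slices = slices, stop_lt = stop_lt, stop_gt = stop_gt,
                 start_ge = start_ge, start_le = start_le,
                 description = description),
            class = "pcc_region_spec")
}

# Per-peptide pooled intensity within a region: observations restricted to
# the region's slice set are summed across slices per sample, averaged over
# the samples in which the peptide was observed at all (absence is
# censoring, not zero), then the per-peptide values of peptides matching
# the coordinate predicates are returned.
region_peptide_values <- function(table, spec, cohorts = NULL) {
  tbl <- tibble::as_tibble(table)
  if (!is.null(cohorts)) tbl <- tbl[tbl$cohort %in% cohorts, , drop = FALSE]
  if (!is.null(spec$slices)) tbl <- tbl[tbl$slice %in% spec$slices, , drop = FALSE]
  keep <- rep(TRUE, nrow(tbl))
  if (!is.null(spec$stop_lt)) keep <- keep & tbl$stop < spec$stop_lt
  if (!is.null(spec$stop_gt)) keep <- keep & tbl$stop > spec$stop_gt
  if (!is.null(spec$start_ge)) keep <- keep & tbl$start >= spec$start_ge
  if (!is.null(spec$start_le)) keep <- keep & tbl$start <= spec$start_le
  tbl <- tbl[keep, , drop = FALSE]
  if (nrow(tbl) == 0) {
    return(tibble::tibble(peptide_seq = character(), start = integer(),
                          stop = integer(), value = numeric()))
  }
  tbl |>
    dplyr::group_by(.data$peptide_seq, .data$start, .data$stop) |>
    dplyr::summarise(
      value = sum(.data$intensity) / dplyr::n_distinct(.data$sample_id),
      .groups = "drop"
    )
}

#' Region intensity ratio across a candidate cleavage boundary
#'
#' The fragment-stoichiometry statistic: per peptide, intensities are
#' summed across the region's gel slices (per sample) and averaged over the
#' samples in which the peptide was observed (a missing observation is
#' censored, not a zero); per region, the per-peptide values are
#' averaged; the ratio is numerator mean over denominator mean.  On data
#' from a cleaved protein with the numerator taken N-terminal and the
#' denominator C-terminal of the cleavage, this estimates the molar excess
#' of the released fragment over its membrane-anchored partner.
#'
#' @param table intensity tibble.
#' @param protein_id protein to analyse.
#' @param numerator,denominator [region_spec()] objects.
#' @param boundary optional residue index recorded with the result (the
#'   region specs themselves carry the coordinate predicates).
#' @param cohorts optional cohort subset (default: all samples pooled).
#' @return one-row tibble: `protein_id`, `boundary`, `ratio`,
#'   `numerator_mean`, `denominator_mean`, `n_numerator`, `n_denominator`,
#'   `numerator_region`, `denominator_region`, `defined`.
#' @export
region_intensity_ratio <- function(table, protein_id, numerator, denominator,
                                   boundary = NA_integer_, cohorts = NULL) {
  tbl <- tibble::as_tibble(table)
  tbl <- tbl[tbl$protein_id == protein_id, , drop = FALSE]
  num <- region_peptide_values(tbl, numerator, cohorts)
  den <- region_peptide_values(tbl, denominator, cohorts)
  defined <- nrow(num) >= 1 && nrow(den) >= 1
  tibble::tibble(
    protein_id = protein_id,
    boundary = as.integer(boundary),
    ratio = if (defined) mean(num$value) / mean(den$value) else NA_real_,
    numerator_mean = if (nrow(num) > 0) mean(num$value) else NA_real_,
    denominator_mean = if (nrow(den) > 0) mean(den$value) else NA_real_,
    n_numerator = nrow(num),
    n_denominator = nrow(den),
    numerator_region = numerator$description,
    denominator_region = denominator$description,
    defined = defined
  )
}

#' Depletion of a C-terminal tail region
#'
#' Mean pooled intensity of peptides starting at or after `tail_start`
#' (summed across all slices, averaged over samples) divided by the mean of
#' a reference region (default: slice-A peptides).  Returns a ratio of 0
#' with `n_tail = 0` when no tail peptide was detected, the signature of a
#' tail removed before vesicle loading.
#'
#' @param table intensity tibble.
#' @param protein_id protein to analyse.
#' @param tail_start first residue of the tail region (e.g. just C-terminal
#'   of the last transmembrane domain).
#' @param reference [region_spec()] for the reference region.
#' @param cohorts optional cohort subset.
#' @return one-row tibble: `protein_id`, `tail_start`, `ratio`, `n_tail`,
#'   `n_reference`.
#' @export
tail_depletion <- function(table, protein_id, tail_start,
                           reference = region_spec(slices = "A"),
                           cohorts = NULL) {
  tbl <- tibble::as_tibble(table)
  tbl <- tbl[tbl$protein_id == protein_id, , drop = FALSE]
  tail <- region_peptide_values(tbl, region_spec(start_ge = tail_start), cohorts)
  ref <- region_peptide_values(tbl, reference, cohorts)
  if (nrow(ref) == 0) stop("reference region contains no peptides", call. = FALSE)
  tibble::tibble(
    protein_id = protein_id,
    tail_start = as.integer(tail_start),
    ratio = if (nrow(tail) == 0) 0 else mean(tail$value) / mean(ref$value),
    n_tail = nrow(tail),
    n_reference = nrow(ref)
  )
}

# Jensen-Shannon divergence (base 2, bounded in [0, 1]) between two
# non-negative weight vectors over the same categories.
js_divergence <- function(p, q) {
  p <- p / sum(p)
  q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Infer cleavage positions from gel-slice change-points
#'
#' Scans candidate boundaries along a protein and scores each by how
#' different the gel-slice distributions of peptides entirely N-terminal
#' versus entirely C-terminal of the boundary are.  The separation
#' statistic is the Jensen-Shannon divergence (JSD) between the two
#' intensity-weighted slice distributions; peptides spanning the boundary
#' are excluded from both sides.  Local maxima above `jsd_min` are emitted
#' as calls.
#'
#' Support enters as a hard gate (`min_support` peptides per side), not as
#' a multiplicative weight: a count-weighted score systematically prefers
#' boundaries shifted into the larger region, because the smaller side's
#' count grows faster than the divergence decays.  Set
#' `weight_by_support = TRUE` to rank by JSD times the smaller side's
#' peptide count instead.
#'
#' Peptide-level data cannot localize a cut more finely than the gap
#' between flanking observed peptides, so every call carries an interval
#' `[interval_start, interval_end]`: the true cut position p (bond between
#' p and p+1) satisfies `interval_start <= p <= interval_end`.  Equal-score
#' adjacent candidates are merged into a single call.
#'
#' @param table intensity tibble.
#' @param protein_id protein to analyse.
#' @param candidates `"tryptic_boundaries"` (default: stops and starts-1 of
#'   observed peptides, the only observable breakpoints), `"all_residues"`,
#'   or a numeric vector of annotated positions.
#' @param min_support minimum peptides on each side of a scored boundary
#'   (default 3).
#' @param jsd_min minimum Jensen-Shannon divergence for a call (default
#'   0.1).
#' @param min_peptides minimum distinct peptides for the protein; below
#'   this an empty result is returned with a warning (default 10).
#' @param weight_by_support multiply the divergence by the smaller side's
#'   peptide count when ranking (default `FALSE`).
#' @return tibble of class `pcc_cleavage_calls`, sorted by decreasing
#'   score: `protein_id`, `position` (midpoint of the interval), `interval_start`,
#'   `interval_end`, `resolution` (`"exact"` when the interval is a single
#'   residue, else `"interval"`), `score`, `jsd`, `n_nterm`, `n_cterm`.
#'   The full score profile is attached as attribute `profile`.
#' @export
infer_cleavage_positions <- function(table, protein_id,
                                     candidates = "tryptic_boundaries",
                                     min_support = 3, jsd_min = 0.1,
                                     min_peptides = 10,
                                     weight_by_support = FALSE) {
  tbl <- tibble::as_tibble(table)
  tbl <- tbl[tbl$protein_id == protein_id & tbl$intensity > 0, , drop = FALSE]

  empty <- tibble::tibble(
    protein_id = character(), position = numeric(), interval_start = integer(),
    interval_end = integer(), resolution = character(), score = numeric(),
    jsd = numeric(), n_nterm = integer(), n_cterm = integer()
  )
  class(empty) <- c("pcc_cleavage_calls", class(empty))

  peptides <- tbl |>
    dplyr::group_by(.data$start, .data$stop, .data$slice) |>
    dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop")
  distinct_peps <- dplyr::distinct(peptides, .data$start, .data$stop)
  if (nrow(distinct_peps) < min_peptides) {
    warning("only ", nrow(distinct_peps), " distinct peptides for ",
            protein_id, "; no cleavage inference")
    return(empty)
  }

  slices <- sort(unique(peptides$slice))
  # peptide x slice intensity matrix (peptides = distinct start/stop)
  pep <- distinct_peps[order(distinct_peps$start, distinct_peps$stop), ]
  key <- paste(pep$start, pep$stop)
  mat <- matrix(0, nrow = nrow(pep), ncol = length(slices),
                dimnames = list(key, slices))
  mat[cbind(match(paste(peptides$start, peptides$stop), key),
            match(peptides$slice, slices))] <- peptides$intensity

  if (is.numeric(candidates)) {
    cand <- sort(unique(as.integer(candidates)))
  } else if (identical(candidates, "all_residues")) {
    cand <- seq(min(pep$start), max(pep$stop) - 1L)
  } else {
    cand <- sort(unique(c(pep$stop, pep$start - 1L)))
    cand <- cand[cand >= min(pep$start) & cand < max(pep$stop)]
  }
  if (length(cand) == 0) return(empty)

  score_one <- function(b) {
    n_side <- pep$stop <= b
    c_side <- pep$start > b
    n_n <- sum(n_side); n_c <- sum(c_side)
    if (n_n < min_support || n_c < min_support) {
      return(c(jsd = NA_real_, score = NA_real_, n_n = n_n, n_c = n_c))
    }
    p <- colSums(mat[n_side, , drop = FALSE])
    q <- colSums(mat[c_side, , drop = FALSE])
    if (sum(p) == 0 || sum(q) == 0) {
      return(c(jsd = NA_real_, score = NA_real_, n_n = n_n, n_c = n_c))
    }
    jsd <- js_divergence(p, q)
    score <- if (weight_by_support) jsd * min(n_n, n_c) else jsd
    c(jsd = jsd, score = score, n_n = n_n, n_c = n_c)
  }
  prof <- t(vapply(cand, score_one, numeric(4)))
  profile <- tibble::tibble(
    candidate = cand, jsd = prof[, "jsd"], score = prof[, "score"],
    n_nterm = as.integer(prof[, "n_n"]), n_cterm = as.integer(prof[, "n_c"])
  )

  ok <- !is.na(profile$score) & profile$jsd >= jsd_min
  if (!any(ok)) {
    attr(empty, "profile") <- profile
    return(empty)
  }

  # local maxima over the scored candidates, with ties (within 1e-9)
  # merged into one interval call
  sc <- profile$score
  sc[is.na(sc)] <- -Inf
  same <- utils::head(sc, -1) == utils::tail(sc, -1) | abs(diff(sc)) <= 1e-9
  same[is.na(same)] <- FALSE
  groups <- cumsum(c(TRUE, !same))
  grp_tbl <- tibble::tibble(idx = seq_along(cand), grp = groups, score = sc)
  grp_scores <- tapply(sc, groups, max)
  is_local_max <- vapply(seq_along(grp_scores), function(g) {
    s <- grp_scores[[g]]
    left <- if (g > 1) grp_scores[[g - 1]] else -Inf
    right <- if (g < length(grp_scores)) grp_scores[[g + 1]] else -Inf
    s > left && s > right || (s >= left && s >= right && length(grp_scores) == 1)
  }, logical(1))

  calls <- purrr::map_dfr(which(is_local_max), function(g) {
    idx <- grp_tbl$idx[grp_tbl$grp == g]
    b_lo <- cand[min(idx)]
    b_hi <- cand[max(idx)]
    if (!ok[min(idx)]) return(NULL)
    # widen to the gap between flanking observed peptides
    lo <- max(pep$stop[pep$stop <= b_lo])
    hi <- min(pep$start[pep$start > b_hi]) - 1L
    tibble::tibble(
      protein_id = protein_id,
      position = (lo + hi) / 2,
      interval_start = as.integer(lo),
      interval_end = as.integer(hi),
      resolution = if (lo == hi) "exact" else "interval",
      score = grp_scores[[g]],
      jsd = max(profile$jsd[idx]),
      n_nterm = profile$n_nterm[idx[1]],
      n_cterm = profile$n_cterm[idx[1]]
    )
  })
  calls <- dplyr::arrange(calls, dplyr::desc(.data$score))
  class(calls) <- c("pcc_cleavage_calls", class(calls))
  attr(calls, "profile") <- profile
  calls
}

#' Enumerate protein fragments implied by cleavage sets
#'
#' Each cleavage set represents one proteoform population; its fragments
#' are the maximal runs between consecutive cleavage positions.  For each
#' fragment the mass is computed under the three deglycosylation
#' treatments, the expected gel slice is assigned per treatment, and the
#' number of fully contained transmembrane features is counted.
#'
#' @param protein single-row protein record table.
#' @param cleavage_sets list of integer vectors of cleavage positions (an
#'   empty vector yields the intact protein); names become population
#'   labels.
#' @param glycans optional glycan tibble (`position`, `state`, `mass_kDa`).
#' @param features optional feature tibble; rows with `kind == "TM"` drive
#'   `tm_count`.
#' @param scheme gel-slice scheme for expected-slice assignment.
#' @return fragment tibble: `protein_id`, `population`, `label`, `start`,
#'   `stop`, `n_residues`, `mass_glyc_kDa`, `mass_endoH_kDa`,
#'   `mass_pngaseF_kDa`, `tm_count`, `expected_slice` (glycosylated),
#'   `expected_slice_endoH`, `expected_slice_pngaseF`.
#' @export
fragment_model <- function(protein, cleavage_sets, glycans = NULL,
                           features = NULL, scheme = gel_slice_scheme()) {
  stopifnot(nrow(protein) == 1)
  len <- protein$length[[1]]
  if (is.null(names(cleavage_sets)) && length(cleavage_sets) > 0) {
    names(cleavage_sets) <- paste0("pop", seq_along(cleavage_sets))
  }
  tm <- if (!is.null(features)) {
    features[features$kind == "TM" & features$protein_id == protein$id[[1]], ]
  } else NULL
  purrr::imap_dfr(cleavage_sets, function(sites, pop) {
    sites <- as.integer(sites)
    if (anyDuplicated(sites)) stop("duplicate cleavage sites in population ", pop, call. = FALSE)
    if (length(sites) > 0 && (any(sites < 1) || any(sites >= len))) {
      stop("cleavage site out of range in population ", pop, call. = FALSE)
    }
    sites <- sort(sites)
    starts <- c(1L, sites + 1L)
    stops <- c(sites, len)
    m_g <- fragment_mass(protein, starts, stops, glycans, "none")
    m_e <- fragment_mass(protein, starts, stops, glycans, "endoH")
    m_p <- fragment_mass(protein, starts, stops, glycans, "pngaseF")
    tibble::tibble(
      protein_id = protein$id[[1]],
      population = pop,
      label = sprintf("%s_%d_%d", pop, starts, stops),
      start = starts, stop = stops,
      n_residues = stops - starts + 1L,
      mass_glyc_kDa = m_g, mass_endoH_kDa = m_e, mass_pngaseF_kDa = m_p,
      tm_count = if (is.null(tm)) NA_integer_ else
        purrr::map2_int(starts, stops, function(s, e) {
          sum(tm$start >= s & tm$end <= e)
        }),
      expected_slice = assign_expected_slice(m_g, scheme),
      expected_slice_endoH = assign_expected_slice(m_e, scheme),
      expected_slice_pngaseF = assign_expected_slice(m_p, scheme)
    )
  })
}

#' Band-mass algebra (contiguity check)
#'
#' Verifies sum/difference constraints among observed gel-band masses, the
#' arithmetic that shows two cleavage products are contiguous pieces of a
#' larger band (e.g. mass(D) + mass(F) = mass(B) within tolerance).
#'
#' Constraints are given as a list of lists with fields `operands`
#' (character vector of band labels, combined left to right), `op`
#' (`"sum"` or `"difference"`), and either `expected_label` (compare to
#' another band) or `expected_kDa` (compare to a number); an optional
#' per-constraint `tolerance_kDa` overrides the default.
#'
#' @param bands tibble with `label` and `mass_kDa`.
#' @param constraints list of constraint lists (see details).
#' @param tolerance_kDa default tolerance, 2 kDa (the scale of gel mass
#'   estimation error).
#' @return tibble: `constraint`, `value_kDa`, `expected_kDa`,
#'   `residual_kDa`, `tolerance_kDa`, `pass`.
#' @export
contiguity_check <- function(bands, constraints, tolerance_kDa = 2) {
  lookup <- stats::setNames(bands$mass_kDa, bands$label)
  get_mass <- function(lbl) {
    if (!lbl %in% names(lookup)) {
      stop("unmatched band label: ", lbl, call. = FALSE)
    }
    lookup[[lbl]]
  }
  purrr::map_dfr(constraints, function(con) {
    op <- match.arg(con$op, c("sum", "difference"))
    vals <- vapply(con$operands, get_mass, numeric(1))
    value <- if (op == "sum") sum(vals) else Reduce(`-`, vals)
    expected <- if (!is.null(con$expected_label)) get_mass(con$expected_label)
    else con$expected_kDa
    if (is.null(expected)) stop("constraint needs expected_label or expected_kDa", call. = FALSE)
    tol <- if (!is.null(con$tolerance_kDa)) con$tolerance_kDa else tolerance_kDa
    tibble::tibble(
      constraint = paste0(paste(con$operands, collapse = if (op == "sum") " + " else " - "),
                          " = ",
                          if (!is.null(con$expected_label)) con$expected_label else expected),
      value_kDa = value,
      expected_kDa = expected,
      residual_kDa = value - expected,
      tolerance_kDa = tol,
      pass = abs(value - expected) <= tol
    )
  })
}

#' Localize cleavage by glycan-mass milestones
#'
#' Given an observed glycosylated-minus-deglycosylated mass shift for a
#' fragment, enumerates every subset of the candidate sequon glycans whose
#' treatment-removable mass matches the shift within tolerance.  Because
#' glycans sit at known sequon positions, the consistent subsets bound
#' where the fragment (and hence the cleavage generating it) can lie.
#'
#' @param shift_kDa observed mass shift in kDa (glycosylated minus
#'   treated).
#' @param glycans tibble with `position`, `state`, `mass_kDa`.
#' @param treatment `"pngaseF"` (removes all N-glycans) or `"endoH"`
#'   (removes `endoH_sensitive` only).
#' @param tolerance_kDa matching tolerance (default 0.5).
#' @return tibble of consistent subsets: `subset` (list-column of sequon
#'   positions), `n_glycans`, `removed_kDa`, `residual_kDa`.
#' @export
localize_by_glycan_milestones <- function(shift_kDa, glycans,
                                          treatment = c("pngaseF", "endoH"),
                                          tolerance_kDa = 0.5) {
  treatment <- match.arg(treatment)
  removable <- switch(treatment,
    pngaseF = glycans,
    endoH = glycans[glycans$state == "endoH_sensitive", , drop = FALSE]
  )
  n <- nrow(removable)
  subsets <- purrr::map(seq_len(2^n) - 1, function(mask) {
    which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
  })
  out <- purrr::map_dfr(subsets, function(idx) {
    removed <- sum(removable$mass_kDa[idx])
    tibble::tibble(
      subset = list(sort(removable$position[idx])),
      n_glycans = length(idx),
      removed_kDa = removed,
      residual_kDa = removed - shift_kDa
    )
  })
  out[abs(out$residual_kDa) <= tolerance_kDa, , drop = FALSE]
}
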
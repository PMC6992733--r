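# Synthetic gel-slice peptide-intensity datasets with known ground truth.
#
# The generator digests a protein in silico, assigns each tryptic peptide to
# the proteoform fragments that contain it, and places each observation in
# the gel slice expected for that fragment's mass.  Populations whose
# fragments co-migrate contribute to one mixed (peptide, slice) ion current;
# noise and detection act on that observation unit, per sample:
#   base * response(peptide) * fraction(population) * retention(fragment)
#     * cohort fold-change (case samples) * 2^N(0, noise_sd_log2),
# thinned per observation by a detection probability.  Per-peptide response
# factors span two decades (log-uniform) to mimic ion-current spread and are
# centred to unit mean within each inter-site segment, so that segment-level
# abundance ratios equal the planted stoichiometries exactly in the
# noise-free limit.

# Approximate vertebrate amino-acid frequencies; K+R ~ 11% gives a mean
# tryptic peptide length around 9 residues.
.AA_FREQ <- c(
  A = 8.3, R = 5.6, N = 4.1, D = 5.4, C = 1.4, Q = 4.0, E = 6.8, G = 7.1,
  H = 2.3, I = 4.4, L = 9.9, K = 5.7, M = 2.1, F = 3.7, P = 6.3, S = 8.3,
  T = 5.3, W = 1.1, Y = 2.7, V = 6.0
)

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Deterministic pseudo-random protein sequence
#'
#' Samples residues from typical amino-acid frequencies (so tryptic
#' peptides average ~9 residues), then plants structure: positions listed
#' in `sites` are forced to leucine (so a cleavage position is never itself
#' a tryptic boundary) and positions in `sequons` are forced to an
#' N-X-S motif.
#'
#' @param length protein length in residues.
#' @param seed RNG seed; the same seed always yields the same sequence.
#' @param sites planned cleavage positions to protect.
#' @param sequons positions at which to plant N-X-S sequons.
#' @return a single amino-acid string.
#' @export
synthetic_protein_sequence <- function(length, seed, sites = integer(),
                                       sequons = integer()) {
  res <- with_seed(seed, {
    sample(names(.AA_FREQ), size = length, replace = TRUE,
           prob = .AA_FREQ / sum(.AA_FREQ))
  })
  for (p in sites) {
    res[p] <- "L"
    if (p + 1 <= length && res[p + 1] == "P") res[p + 1] <- "T"
  }
  for (p in sequons) {
    stopifnot(p + 2 <= length)
    res[p] <- "N"
    if (res[p + 1] == "P") res[p + 1] <- "A"
    res[p + 2] <- "S"
  }
  paste(res, collapse = "")
}

#' Assemble and validate a synthetic dataset configuration
#'
#' @param proteins protein record table.
#' @param populations tibble with one row per proteoform population:
#'   `protein_id`, `population`, `fraction` (molar fractions summing to 1
#'   per protein), `sites` (list-column of cleavage position vectors) and
#'   `multipliers` (list-column of per-fragment retention multipliers, one
#'   more than the number of sites, in N- to C-terminal order; a retention
#'   of 0 removes the fragment, values above 1 encode super-stoichiometric
#'   retention such as ectodomain excess).
#' @param cohort_fc named numeric vector of per-protein case/control
#'   fold-changes.
#' @param n_case,n_control cohort sizes (defaults 13 and 18).
#' @param noise_sd_log2 multiplicative log-normal noise sd in log2 units
#'   (default 0.5).
#' @param detect_prob per-observation detection probability (default 0.8).
#' @param abundance_decades spread of per-peptide response factors in
#'   log10 decades (default 2; 0 gives identical responses).
#' @param base_intensity ion-current scale (arbitrary units, default 1e6).
#' @param mass_range monoisotopic detectability window in Da (default
#'   700-4000).
#' @param scheme gel-slice scheme.
#' @param seed mandatory integer seed.
#' @param planted optional named list of planted quantities, kept with the
#'   ground truth for recovery tests.
#' @return object of class `pcc_synthetic_config`.
#' @export
synthetic_config <- function(proteins, populations, cohort_fc,
                             n_case = 13, n_control = 18,
                             noise_sd_log2 = 0.5, detect_prob = 0.8,
                             abundance_decades = 2, base_intensity = 1e6,
                             mass_range = c(700, 4000),
                             scheme = gel_slice_scheme(), seed,
                             planted = list()) {
  if (missing(seed)) stop("synthetic_config requires an explicit seed", call. = FALSE)
  populations <- tibble::as_tibble(populations)
  stopifnot(all(c("protein_id", "population", "fraction", "sites",
                  "multipliers") %in% names(populations)))
  for (pid in unique(populations$protein_id)) {
    pp <- populations[populations$protein_id == pid, ]
    if (abs(sum(pp$fraction) - 1) > 1e-8) {
      stop("molar fractions for ", pid, " must sum to 1", call. = FALSE)
    }
    for (i in seq_len(nrow(pp))) {
      ns <- length(pp$sites[[i]])
      if (length(pp$multipliers[[i]]) != ns + 1) {
        stop("population ", pp$population[i], " of ", pid,
             " needs ", ns + 1, " fragment multipliers", call. = FALSE)
      }
      if (any(pp$multipliers[[i]] < 0)) stop("multipliers must be >= 0", call. = FALSE)
    }
  }
  if (noise_sd_log2 < 0) stop("noise_sd_log2 must be >= 0", call. = FALSE)
  if (detect_prob <= 0 || detect_prob > 1) {
    stop("detect_prob must be in (0, 1]", call. = FALSE)
  }
  if (!all(unique(populations$protein_id) %in% proteins$id)) {
    stop("populations reference unknown proteins", call. = FALSE)
  }
  structure(list(
    proteins = proteins, populations = populations,
    cohort_fc = cohort_fc, n_case = n_case, n_control = n_control,
    noise_sd_log2 = noise_sd_log2, detect_prob = detect_prob,
    abundance_decades = abundance_decades, base_intensity = base_intensity,
    mass_range = mass_range, scheme = scheme, seed = as.integer(seed),
    planted = planted
  ), class = "pcc_synthetic_config")
}

#' Simulate a two-cohort gel-slice peptide intensity table
#'
#' Deterministic given the configuration seed: identical configs yield
#' byte-identical tables.  The planted parameters, the per-population
#' fragment model and the configuration itself are attached as attribute
#' `ground_truth` for parameter-recovery tests.
#'
#' @param config a `pcc_synthetic_config` from [synthetic_config()] or
#'   [pcc_preset()].
#' @return intensity tibble (columns as [read_intensity_table()]) with
#'   attributes `scheme` and `ground_truth`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "pcc_synthetic_config"))
  scheme <- config$scheme
  samples <- tibble::tibble(
    sample_id = c(sprintf("PKD1_%02d", seq_len(config$n_case)),
                  sprintf("NORM_%02d", seq_len(config$n_control))),
    cohort = c(rep("PKD1", config$n_case), rep("normal", config$n_control))
  )

  result <- with_seed(config$seed, {
    purrr::map_dfr(seq_len(nrow(config$proteins)), function(pi) {
      protein <- config$proteins[pi, ]
      pid <- protein$id[[1]]
      pops <- config$populations[config$populations$protein_id == pid, ]
      if (nrow(pops) == 0) return(NULL)
      peptides <- digest_protein(protein, max_missed = 0,
                                 mass_range = config$mass_range)
      fc <- if (pid %in% names(config$cohort_fc)) config$cohort_fc[[pid]] else 1

      # per-population fragment tables with slice and retention multiplier
      frags <- purrr::map_dfr(seq_len(nrow(pops)), function(k) {
        sites <- sort(as.integer(pops$sites[[k]]))
        fr <- fragment_model(protein, stats::setNames(list(sites), pops$population[k]),
                             scheme = scheme)
        fr$fraction <- pops$fraction[k]
        fr$multiplier <- pops$multipliers[[k]]
        fr
      })

      # peptide -> fragment containment per population
      assign_tbl <- purrr::map_dfr(seq_len(nrow(frags)), function(f) {
        inside <- peptides$start >= frags$start[f] & peptides$stop <= frags$stop[f]
        if (!any(inside)) return(NULL)
        tibble::tibble(
          pep_idx = which(inside),
          population = frags$population[f],
          slice = frags$expected_slice[f],
          level = frags$fraction[f] * frags$multiplier[f]
        )
      })
      assign_tbl <- assign_tbl[assign_tbl$level > 0 &
                                 assign_tbl$slice != "out_of_range", , drop = FALSE]
      if (nrow(assign_tbl) == 0) return(NULL)

      # the observation unit is (peptide, slice): proteoform populations
      # co-migrating in a slice contribute to one mixed ion current
      assign_tbl <- assign_tbl |>
        dplyr::group_by(.data$pep_idx, .data$slice) |>
        dplyr::summarise(level = sum(.data$level), .groups = "drop") |>
        dplyr::arrange(.data$pep_idx, .data$slice)

      observed <- sort(unique(assign_tbl$pep_idx))

      # per-peptide response factors, log-uniform over abundance_decades,
      # centred within inter-site segments (union of all sites)
      site_union <- sort(unique(unlist(pops$sites)))
      seg_start <- c(1L, site_union + 1L)
      seg_stop <- c(site_union, protein$length[[1]])
      seg_of <- vapply(observed, function(i) {
        hit <- which(peptides$start[i] >= seg_start & peptides$stop[i] <= seg_stop)
        if (length(hit) == 1) hit else 0L  # 0 = spans a segment boundary
      }, integer(1))
      u <- stats::runif(length(observed))
      b <- 10^(config$abundance_decades * u)
      for (g in unique(seg_of)) {
        idx <- seg_of == g
        b[idx] <- b[idx] / mean(b[idx])
      }
      response <- stats::setNames(b, observed)

      # observation grid in fixed order: assignment row x sample
      grid <- tidyr::crossing(
        assign_tbl |> dplyr::mutate(row = dplyr::row_number()),
        samples
      ) |> dplyr::arrange(.data$row, .data$sample_id)
      n <- nrow(grid)
      noise <- 2^stats::rnorm(n, mean = 0, sd = config$noise_sd_log2)
      detected <- stats::runif(n) < config$detect_prob
      grid$intensity <- config$base_intensity *
        unname(response[as.character(grid$pep_idx)]) * grid$level *
        ifelse(grid$cohort == "PKD1", fc, 1) * noise
      grid <- grid[detected, , drop = FALSE]
      if (nrow(grid) == 0) return(NULL)

      grid |>
        dplyr::transmute(
          protein_id = pid,
          peptide_seq = peptides$sequence[.data$pep_idx],
          start = peptides$start[.data$pep_idx],
          stop = peptides$stop[.data$pep_idx],
          slice = .data$slice, sample_id = .data$sample_id,
          cohort = .data$cohort, intensity = .data$intensity
        )
    })
  })

  result <- dplyr::arrange(result, .data$protein_id, .data$start, .data$stop,
                           .data$slice, .data$sample_id)
  attr(result, "scheme") <- scheme

  gt_frags <- purrr::map_dfr(seq_len(nrow(config$proteins)), function(pi) {
    protein <- config$proteins[pi, ]
    pops <- config$populations[config$populations$protein_id == protein$id[[1]], ]
    purrr::map_dfr(seq_len(nrow(pops)), function(k) {
      fr <- fragment_model(protein,
                           stats::setNames(list(sort(as.integer(pops$sites[[k]]))),
                                           pops$population[k]),
                           scheme = config$scheme)
      fr$fraction <- pops$fraction[k]
      fr$multiplier <- pops$multipliers[[k]]
      fr
    })
  })
  attr(result, "ground_truth") <- list(
    config = config, fragments = gt_frags, planted = config$planted
  )
  result
}

# ---- frozen synthetic study proteins -------------------------------------

.synth_pc1 <- function() {
  seq <- synthetic_protein_sequence(
    4302, seed = 101,
    sites = c(3048L, 3588L, 3760L, 4200L),
    sequons = c(3738L, 3790L, 3845L)
  )
  proteins <- protein_records("PC1S", seq, name = "synthetic polycystin-1-like")
  tm <- rbind(
    c(3080, 3102), c(3130, 3152), c(3400, 3422), c(3560, 3582),
    c(3600, 3622), c(3650, 3672), c(4000, 4022), c(4050, 4072),
    c(4090, 4112), c(4130, 4152), c(4160, 4182)
  )
  features <- tibble::tibble(
    protein_id = "PC1S",
    kind = c(rep("TM", 11), "coiled_coil", "annotated_cleavage"),
    start = c(tm[, 1], 4220, 3048),
    end = c(tm[, 2], 4260, 3048),
    label = c(paste0("TM", 1:11), "coiled_coil", "GPS")
  )
  glycans <- tibble::tibble(
    protein_id = "PC1S",
    position = c(3738L, 3790L, 3845L),
    state = c("endoH_sensitive", "mature", "mature"),
    mass_kDa = c(2, 5, 5)
  )
  list(proteins = proteins, features = features, glycans = glycans)
}

.synth_fibrocystin <- function() {
  seq <- synthetic_protein_sequence(4074, seed = 102, sites = c(3616L, 3881L))
  proteins <- protein_records("FCYS", seq, name = "synthetic fibrocystin-like")
  features <- tibble::tibble(
    protein_id = "FCYS",
    kind = c("TM", "annotated_cleavage"),
    start = c(3859, 3616), end = c(3881, 3616),
    label = c("TM", "PPC")
  )
  list(proteins = proteins, features = features, glycans = NULL)
}

.synth_pc2 <- function() {
  seq <- synthetic_protein_sequence(968, seed = 103, sites = 806L)
  proteins <- protein_records("PC2S", seq, name = "synthetic polycystin-2-like")
  features <- tibble::tibble(
    protein_id = "PC2S",
    kind = c("domain", "coiled_coil"),
    start = c(750, 833), end = c(785, 872),
    label = c("EF_hand", "coiled_coil")
  )
  list(proteins = proteins, features = features, glycans = NULL)
}

.synth_cemip2 <- function() {
  seq <- synthetic_protein_sequence(1383, seed = 104)
  proteins <- protein_records("CEM2S", seq, name = "synthetic CEMIP2/TMEM2-like")
  list(proteins = proteins, features = NULL, glycans = NULL)
}

#' Frozen synthetic study presets
#'
#' Returns a [synthetic_config()] emulating one slice-proteomics scenario
#' from the urinary-ELV polycystin study, with planted parameters matched
#' to the published pooled-intensity statistics:
#'
#' * `pc1_fig1`: PC1-like protein, complete GPS/GAIN cleavage at 3048,
#'   ectodomain retained at 1.4x the C-terminal fragment, cohort
#'   fold-change 0.5 (decreased in PKD1).
#' * `pc1_fig2`: as above plus a 60% sub-population carrying the three
#'   further C-terminal cuts (TM-IV/V hairpin, TOP-domain loop, C-terminal
#'   trim), spreading C-terminal peptides over several slices.
#' * `fibrocystin_ppc`: fibrocystin-like protein, PPC cleavage at 3616
#'   with the post-PPC region depleted so that the published 58%
#'   pooled-ratio is the planted value, plus near-complete C-terminal tail
#'   removal at the TM leaving the tail at 5.1% of the slice-A reference;
#'   cohort fold-change 0.67.
#' * `pc2_tail`: PC2-like protein, a minority proteoform (11.5%) with the
#'   C-terminal tail released ahead of the coiled-coil, so that the tail
#'   region's slice I-J intensity is 13% of its slice A-D intensity.
#' * `cemip2_null`: uncleaved control protein, increased in PKD1 (fold 2).
#'
#' The retention multiplier of the fibrocystin mid-region is calibrated at
#' build time (from the fixed in-silico digest) so that the pooled
#' region-ratio statistic over slices B-J equals 58% exactly in the
#' noise-free limit; the calibration accounts for the low-level tail
#' peptides included in that region.
#'
#' @param name one of `"pc1_fig1"`, `"pc1_fig2"`, `"fibrocystin_ppc"`,
#'   `"pc2_tail"`, `"cemip2_null"`.
#' @param seed simulation seed (default 1); the protein sequences are fixed
#'   independently of this seed.
#' @param ... overrides passed on to [synthetic_config()] (e.g.
#'   `noise_sd_log2 = 0`, `detect_prob = 1`).
#' @return a `pcc_synthetic_config`; planted values are in `$planted` and
#'   the protein annotation tables in `$annotation`.
#' @export
pcc_preset <- function(name, seed = 1, ...) {
  known <- c("pc1_fig1", "pc1_fig2", "fibrocystin_ppc", "pc2_tail", "cemip2_null")
  if (!name %in% known) {
    stop("unknown preset '", name, "'; available: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  build <- function(ann, populations, cohort_fc, planted, ...) {
    cfg <- synthetic_config(ann$proteins, populations, cohort_fc,
                            seed = seed, planted = planted, ...)
    cfg$annotation <- ann
    cfg$preset <- name
    cfg
  }
  switch(name,
    pc1_fig1 = build(
      .synth_pc1(),
      tibble::tibble(
        protein_id = "PC1S", population = "gps_only", fraction = 1,
        sites = list(3048L), multipliers = list(c(1.4, 1))
      ),
      c(PC1S = 0.5),
      planted = list(site = 3048L, ecto_ctf_ratio = 1.4, cohort_fc = 0.5),
      ...
    ),
    pc1_fig2 = build(
      .synth_pc1(),
      tibble::tibble(
        protein_id = "PC1S",
        population = c("gps_only", "fully_processed"),
        fraction = c(0.4, 0.6),
        sites = list(3048L, c(3048L, 3588L, 3760L, 4200L)),
        multipliers = list(c(1.4, 1), c(1.4, 1, 1, 1, 0.05))
      ),
      c(PC1S = 0.5),
      planted = list(site = 3048L, ecto_ctf_ratio = 1.4, cohort_fc = 0.5),
      ...
    ),
    fibrocystin_ppc = {
      ann <- .synth_fibrocystin()
      # Calibrate the mid-region retention so the pooled B-J/slice-A ratio
      # statistic equals 58% in expectation.  The B-J region includes the
      # residual 5.1% tail peptides, and mid-region peptides are observed
      # in two slices (the tail-cleaved and tail-retained proteoforms), so
      # their censored-mean value carries the two-slice detection factor
      # p / (1 - (1 - p)^2) relative to single-slice peptides.
      dots <- list(...)
      p_det <- if (!is.null(dots$detect_prob)) dots$detect_prob else 0.8
      phi2 <- p_det / (1 - (1 - p_det)^2)
      peptides <- digest_protein(ann$proteins, max_missed = 0,
                                 mass_range = c(700, 4000))
      n_mid <- sum(peptides$start >= 3617 & peptides$stop <= 3881)
      n_tail <- sum(peptides$start >= 3882)
      n_span <- sum(peptides$start >= 3617 & peptides$start <= 3881 &
                      peptides$stop > 3881)
      n_all <- n_mid + n_tail + n_span
      tail_level <- 0.1 * 0.51  # fraction x retention of the tail-retained form
      r_mid <- ((0.58 * n_all - 0.051 * (n_span + n_tail)) / n_mid / phi2 -
                  tail_level) / 0.9
      build(
        ann,
        tibble::tibble(
          protein_id = "FCYS",
          population = c("tail_cleaved", "tail_retained"),
          fraction = c(0.9, 0.1),
          sites = list(c(3616L, 3881L), 3616L),
          multipliers = list(c(1, r_mid, 0), c(1, 0.51))
        ),
        c(FCYS = 0.67),
        planted = list(site = 3616L, post_ppc_pct = 58, tail_pct = 5.1,
                       tail_start = 3882L, cohort_fc = 0.67),
        ...
      )
    },
    pc2_tail = build(
      .synth_pc2(),
      tibble::tibble(
        protein_id = "PC2S",
        population = c("intact", "tail_released"),
        fraction = c(0.885, 0.115),
        sites = list(integer(), 806L),
        multipliers = list(1, c(1, 1))
      ),
      c(PC2S = 0.6),
      planted = list(site = 806L, tail_start = 807L,
                     tail_vs_body_pct = 100 * 0.115 / 0.885, cohort_fc = 0.6),
      ...
    ),
    cemip2_null = build(
      .synth_cemip2(),
      tibble::tibble(
        protein_id = "CEM2S", population = "intact", fraction = 1,
        sites = list(integer()), multipliers = list(1)
      ),
      c(CEM2S = 2),
      planted = list(cohort_fc = 2),
      ...
    )
  )
}
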
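# Region ratios, tail depletion, change-point localization, fragment
# models, band algebra and glycan milestones.

test_that("uniform intensities give ratio 1 for any region pair", {
  tab <- dplyr::bind_rows(
    make_intensity_rows("P", seq(1, 91, 10), seq(9, 99, 10), "A", "S1", "PKD1", 1),
    make_intensity_rows("P", seq(101, 191, 10), seq(109, 199, 10), "B", "S1", "PKD1", 1)
  )
  r <- region_intensity_ratio(tab, "P",
                              numerator = region_spec(slices = "A", stop_lt = 100),
                              denominator = region_spec(slices = "B", stop_gt = 100))
  expect_equal(r$ratio, 1.0)
  r2 <- region_intensity_ratio(tab, "P",
                               numerator = region_spec(start_ge = 1),
                               denominator = region_spec(slices = c("A", "B")))
  expect_equal(r2$ratio, 1.0)
})

test_that("empty regions are flagged, not silently computed", {
  tab <- make_intensity_rows("P", 1, 9, "A", "S1", "PKD1", 5)
  r <- region_intensity_ratio(tab, "P",
                              numerator = region_spec(slices = "J"),
                              denominator = region_spec(slices = "A"))
  expect_false(r$defined)
  expect_true(is.na(r$ratio))
  expect_equal(r$n_numerator, 0L)
})

test_that("noise-free generator output recovers planted ratios exactly", {
  # all stochastic elements off: no noise, full detection, flat responses
  cfg <- pcc_preset("pc1_fig1", seed = 2, noise_sd_log2 = 0, detect_prob = 1,
                    abundance_decades = 0)
  tab <- simulate_dataset(cfg)
  # all samples identical up to the cohort fold-change
  per_sample <- tab |>
    dplyr::group_by(cohort, sample_id) |>
    dplyr::summarise(total = sum(intensity), .groups = "drop") |>
    dplyr::group_by(cohort) |>
    dplyr::summarise(n_distinct_totals = dplyr::n_distinct(round(total, 6)),
                     .groups = "drop")
  expect_true(all(per_sample$n_distinct_totals == 1))
  r <- region_intensity_ratio(
    tab, "PC1S",
    numerator = region_spec(slices = "A", stop_lt = 3048),
    denominator = region_spec(slices = LETTERS[2:10], stop_gt = 3048),
    boundary = 3048
  )
  expect_equal(r$ratio, 1.4, tolerance = 1e-12)

  # with log-uniform responses (the default) the segment centring keeps the
  # noise-free ratio exact
  cfg2 <- pcc_preset("pc1_fig1", seed = 3, noise_sd_log2 = 0, detect_prob = 1)
  r2 <- region_intensity_ratio(
    simulate_dataset(cfg2), "PC1S",
    numerator = region_spec(slices = "A", stop_lt = 3048),
    denominator = region_spec(slices = LETTERS[2:10], stop_gt = 3048)
  )
  expect_equal(r2$ratio, 1.4, tolerance = 1e-12)
})

test_that("noise-free fibrocystin and PC2 statistics equal their planted values", {
  cfgf <- pcc_preset("fibrocystin_ppc", seed = 2, noise_sd_log2 = 0, detect_prob = 1)
  tabf <- simulate_dataset(cfgf)
  r <- region_intensity_ratio(
    tabf, "FCYS",
    numerator = region_spec(slices = LETTERS[2:10], stop_gt = 3616),
    denominator = region_spec(slices = "A", stop_lt = 3616)
  )
  expect_equal(r$ratio, 0.58, tolerance = 1e-10)
  td <- tail_depletion(tabf, "FCYS", tail_start = 3882)
  expect_equal(td$ratio, 0.051, tolerance = 1e-10)

  cfg2 <- pcc_preset("pc2_tail", seed = 2, noise_sd_log2 = 0, detect_prob = 1)
  tab2 <- simulate_dataset(cfg2)
  r6 <- region_intensity_ratio(
    tab2, "PC2S",
    numerator = region_spec(slices = c("I", "J"), start_ge = 807),
    denominator = region_spec(slices = LETTERS[1:4], start_ge = 807)
  )
  expect_equal(r6$ratio, 0.115 / 0.885, tolerance = 1e-10)
})

test_that("tail depletion returns 0 with n = 0 when no tail peptides exist", {
  tab <- make_intensity_rows("P", c(1, 11), c(9, 19), "A", "S1", "PKD1", c(5, 5))
  td <- tail_depletion(tab, "P", tail_start = 100)
  expect_equal(td$ratio, 0)
  expect_equal(td$n_tail, 0L)
  expect_error(tail_depletion(tab, "P", 100, reference = region_spec(slices = "J")),
               "reference region contains no peptides")
})

test_that("an uncleaved protein yields no cleavage calls", {
  tab <- simulate_dataset(pcc_preset("cemip2_null", seed = 6))
  calls <- infer_cleavage_positions(tab, "CEM2S")
  expect_equal(nrow(calls), 0)
})

test_that("too few peptides: empty result with warning", {
  tab <- make_intensity_rows("P", c(1, 11, 21), c(9, 19, 29), "A", "S1", "PKD1", 1)
  expect_warning(calls <- infer_cleavage_positions(tab, "P"), "distinct peptides")
  expect_equal(nrow(calls), 0)
})

test_that("planted cleavages are recovered within the flanking-peptide interval", {
  for (s in 1:3) {
    tab <- simulate_dataset(pcc_preset("pc1_fig1", seed = s))
    top <- infer_cleavage_positions(tab, "PC1S")[1, ]
    expect_true(top$interval_start <= 3048 && top$interval_end >= 3048,
                info = paste("pc1 seed", s))
  }
  for (s in 1:3) {
    tab <- simulate_dataset(pcc_preset("fibrocystin_ppc", seed = s))
    top <- infer_cleavage_positions(tab, "FCYS")[1, ]
    expect_true(top$interval_start <= 3616 && top$interval_end >= 3616,
                info = paste("fibrocystin seed", s))
  }
})

test_that("annotated candidate positions are honoured", {
  tab <- simulate_dataset(pcc_preset("pc1_fig1", seed = 4))
  calls <- infer_cleavage_positions(tab, "PC1S", candidates = c(1500L, 3048L))
  expect_equal(nrow(calls), 1)
  expect_true(calls$interval_start <= 3048 && calls$interval_end >= 3048)
})

test_that("added noise does not increase the true boundary's separation score on average", {
  score_at_true <- function(noise_sd, seeds) {
    vapply(seeds, function(s) {
      cfg <- pcc_preset("pc1_fig1", seed = s, noise_sd_log2 = noise_sd)
      tab <- simulate_dataset(cfg)
      calls <- infer_cleavage_positions(tab, "PC1S")
      prof <- attr(calls, "profile")
      max(prof$score[prof$candidate >= 3040 & prof$candidate <= 3056], na.rm = TRUE)
    }, numeric(1))
  }
  lo <- mean(score_at_true(0.25, 11:16))
  hi <- mean(score_at_true(1.5, 11:16))
  expect_gte(lo, hi - 1e-9)
})

test_that("fragment model enumerates, measures and places fragments", {
  pre <- pcc_preset("pc1_fig1")
  ann <- pre$annotation
  prot <- ann$proteins
  # empty cleavage set: the intact protein
  whole <- fragment_model(prot, list(intact = integer()), features = ann$features)
  expect_equal(nrow(whole), 1)
  expect_equal(whole$n_residues, prot$length)
  expect_equal(whole$tm_count, 11L)

  fr <- fragment_model(prot, list(gps = 3048L), glycans = ann$glycans,
                       features = ann$features)
  expect_equal(nrow(fr), 2)
  expect_equal(fr$start, c(1L, 3049L))
  expect_equal(fr$stop, c(3048L, 4302L))
  expect_equal(fr$tm_count, c(0L, 11L))
  expect_equal(sum(fr$n_residues), prot$length)
  # masses shrink (weakly) under stronger deglycosylation
  expect_true(all(fr$mass_glyc_kDa >= fr$mass_endoH_kDa))
  expect_true(all(fr$mass_endoH_kDa >= fr$mass_pngaseF_kDa))
  # the CTF carries 2 kDa Endo H-sensitive + 10 kDa mature glycan
  ctf <- fr[fr$start == 3049, ]
  expect_equal(ctf$mass_glyc_kDa - ctf$mass_pngaseF_kDa, 12)
  expect_equal(ctf$mass_glyc_kDa - ctf$mass_endoH_kDa, 2)

  expect_error(fragment_model(prot, list(dup = c(100L, 100L))), "duplicate")
  expect_error(fragment_model(prot, list(bad = 99999L)), "out of range")
})

test_that("fragments partition the protein and masses add up", {
  pre <- pcc_preset("pc1_fig2")
  prot <- pre$annotation$proteins
  sites <- c(3048L, 3588L, 3760L, 4200L)
  fr <- fragment_model(prot, list(full = sites))
  expect_equal(nrow(fr), 5)
  expect_equal(sum(fr$n_residues), prot$length)
  expect_equal(fr$start[-1], head(fr$stop, -1) + 1L)
  water_kDa <- 18.01528 / 1000
  whole <- fragment_model(prot, list(intact = integer()))
  expect_equal(sum(fr$mass_pngaseF_kDa) - 4 * water_kDa,
               whole$mass_pngaseF_kDa, tolerance = 1e-9)
})

test_that("band algebra reproduces the printed contiguity sums", {
  bands <- tibble::tibble(label = c("B", "C", "D", "F"),
                          mass_kDa = c(81, 70, 52, 29))
  rep1 <- contiguity_check(bands, list(
    list(operands = c("D", "F"), op = "sum", expected_label = "B"),
    list(operands = c("B", "C"), op = "difference", expected_kDa = 11)
  ))
  expect_true(all(rep1$pass))
  expect_equal(rep1$residual_kDa, c(0, 0))

  bad <- contiguity_check(
    tibble::tibble(label = c("X", "Y", "B"), mass_kDa = c(50, 20, 81)),
    list(list(operands = c("X", "Y"), op = "sum", expected_label = "B"))
  )
  expect_false(bad$pass)
  expect_equal(bad$residual_kDa, -11)

  expect_error(contiguity_check(bands, list(
    list(operands = c("D", "Q"), op = "sum", expected_kDa = 81)
  )), "unmatched band label: Q")
})

test_that("glycan milestone subsets match exhaustive enumeration", {
  gl <- tibble::tibble(position = c(10L, 20L, 30L),
                       state = c("endoH_sensitive", "mature", "mature"),
                       mass_kDa = c(2, 5, 5))
  full <- localize_by_glycan_milestones(12, gl)
  expect_equal(nrow(full), 1)
  expect_equal(full$subset[[1]], c(10L, 20L, 30L))

  ten <- localize_by_glycan_milestones(10, gl)
  expect_equal(nrow(ten), 1)
  expect_equal(ten$subset[[1]], c(20L, 30L))

  expect_equal(nrow(localize_by_glycan_milestones(3, gl)), 0)

  # Endo H can only remove the sensitive site
  eh <- localize_by_glycan_milestones(2, gl, treatment = "endoH")
  expect_equal(eh$subset[[1]], 10L)
  expect_equal(nrow(localize_by_glycan_milestones(10, gl, treatment = "endoH")), 0)

  set.seed(14)
  for (i in 1:20) {
    k <- sample(1:6, 1)
    masses <- round(runif(k, 0.5, 8), 2)
    gl2 <- tibble::tibble(position = seq_len(k) * 10L,
                          state = "mature", mass_kDa = masses)
    shift <- round(runif(1, 0, sum(masses)), 2)
    got <- localize_by_glycan_milestones(shift, gl2, tolerance_kDa = 0.5)
    want <- ref_glycan_subsets(masses, shift, 0.5)
    expect_equal(nrow(got), length(want), info = paste("case", i))
    if (length(want) > 0) {
      expect_setequal(
        vapply(got$subset, paste, character(1), collapse = ","),
        vapply(want, function(idx) paste(sort(idx * 10L), collapse = ","), character(1))
      )
    }
  }
})
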
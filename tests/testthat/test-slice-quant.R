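# Gel-slice scheme, intensity table IO, differential analysis and
# peptide/slice consistency.

test_that("default scheme tiles 10-500 kDa, heavy to light", {
  sch <- gel_slice_scheme()
  expect_equal(sch$slice, LETTERS[1:10])
  expect_equal(sch$max_kDa[1], 500)
  expect_equal(sch$min_kDa[10], 10)
  # contiguous tiling: each window's max equals the previous window's min
  expect_equal(sch$max_kDa[-1], sch$min_kDa[-10])
  expect_error(gel_slice_scheme(tibble::tibble(
    slice = c("A", "B"), min_kDa = c(100, 90), max_kDa = c(200, 150)
  )), "overlap")
})

test_that("mass-to-slice assignment: boundaries go to the heavier window", {
  expect_equal(assign_expected_slice(145), "B")
  expect_equal(assign_expected_slice(5), "out_of_range")
  expect_equal(assign_expected_slice(600), "out_of_range")
  expect_equal(assign_expected_slice(270), "A")  # boundary -> heavier
  expect_equal(assign_expected_slice(140), "B")
  expect_equal(assign_expected_slice(500), "A")  # top window closed
  expect_equal(assign_expected_slice(10), "J")
})

test_that("every mass falls in exactly one window or out_of_range", {
  sch <- gel_slice_scheme()
  set.seed(3)
  masses <- runif(1000, 0, 600)
  lab <- assign_expected_slice(masses, sch)
  for (i in seq_along(masses)) {
    m <- masses[i]
    n_windows <- sum(m >= sch$min_kDa & m < sch$max_kDa) +
      (m == 500)  # closure of the top bound
    if (lab[i] == "out_of_range") expect_equal(n_windows, 0)
    else expect_equal(n_windows, 1)
  }
})

test_that("intensity table round trips through disk", {
  tab <- simulate_dataset(pcc_preset("pc2_tail", seed = 4))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_intensity_table(tab, f)
  back <- read_intensity_table(f)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$intensity, tab$intensity, tolerance = 1e-12)
  expect_equal(back$start, tab$start)
  # csv flavour too
  fc <- withr::local_tempfile(fileext = ".csv")
  write_intensity_table(tab, fc)
  expect_equal(nrow(read_intensity_table(fc)), nrow(tab))
})

test_that("table validation drops bad rows and rejects structural errors", {
  ok <- make_intensity_rows("P", c(1, 10), c(5, 18), c("A", "B"),
                            c("S1", "S1"), "PKD1", c(10, 20))
  expect_equal(nrow(validate_intensity_table(ok)), 2)

  withbad <- dplyr::bind_rows(ok, make_intensity_rows("P", 20, 25, "C", "S1", "PKD1", -5))
  expect_message(out <- validate_intensity_table(withbad), "dropped 1 invalid")
  expect_equal(nrow(out), 2)

  expect_error(validate_intensity_table(dplyr::select(ok, -cohort)), "missing column")
  badslice <- make_intensity_rows("P", 1, 5, "Z", "S1", "PKD1", 1)
  expect_error(validate_intensity_table(badslice), "unknown gel slice label.*Z")
  dup <- dplyr::bind_rows(ok, ok[1, ])
  expect_error(validate_intensity_table(dup), "duplicated")
})

test_that("identical cohorts give null p-values, nothing passes", {
  vals <- rep(c(100, 120, 90, 110, 105), 2)
  tab <- make_intensity_rows("P", 1, 9, "A",
                             sprintf("S%02d", 1:10),
                             rep(c("PKD1", "normal"), each = 5),
                             vals)
  res <- differential_peptides(tab)
  expect_equal(res$log2_ratio, 0, tolerance = 1e-12)
  expect_gt(res$p_value, 0.99)
  expect_false(any(res$passes_threshold))
})

test_that("a planted two-fold decrease is recovered within 0.1 log2 units", {
  prot <- protein_records("DP", synthetic_protein_sequence(600, seed = 31))
  cfg <- synthetic_config(
    prot,
    tibble::tibble(protein_id = "DP", population = "intact", fraction = 1,
                   sites = list(integer()), multipliers = list(1)),
    cohort_fc = c(DP = 0.5), noise_sd_log2 = 0.1, detect_prob = 1, seed = 77
  )
  tab <- simulate_dataset(cfg)
  res <- differential_peptides(tab)
  expect_true(all(abs(res$log2_ratio - (-1)) < 0.1 + 0.3))  # individual keys
  expect_equal(mean(res$log2_ratio), -1, tolerance = 0.1)
  expect_gt(mean(res$passes_threshold), 0.9)
})

test_that("degenerate cohorts yield undefined p-values, no crash", {
  tab <- make_intensity_rows("P", 1, 9, "A", c("S1", "S2", "S3"),
                             c("PKD1", "normal", "normal"), c(10, 20, 30))
  res <- differential_peptides(tab)
  expect_true(is.na(res$p_value))
  expect_false(res$passes_threshold)
  # empty table
  empty <- differential_peptides(make_intensity_rows("P", 1, 2, "A", "S", "PKD1", 1)[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("Welch and pooled t-tests agree with a reference implementation", {
  set.seed(1234)
  n_keys <- 1000
  rows <- purrr::map_dfr(seq_len(n_keys), function(i) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    make_intensity_rows("P", i * 10, i * 10 + 5, "A",
                        sprintf("S%d_%d", i, seq_len(nx + ny)),
                        rep(c("PKD1", "normal"), c(nx, ny)),
                        2^rnorm(nx + ny, 10, 1))
  })
  for (ve in c(FALSE, TRUE)) {
    res <- differential_peptides(rows, var_equal = ve)
    ref <- rows |>
      dplyr::group_by(start, stop) |>
      dplyr::summarise(p_ref = ref_t_test_p(
        log2(intensity[cohort == "PKD1"]),
        log2(intensity[cohort == "normal"]), var_equal = ve
      ), .groups = "drop")
    j <- dplyr::inner_join(res, ref, by = c("start", "stop"))
    expect_equal(nrow(j), n_keys)
    expect_lt(max(abs(j$p_value - j$p_ref)), 1e-10)
  }
})

test_that("BH adjustment is available but off by default", {
  set.seed(9)
  rows <- purrr::map_dfr(1:20, function(i) {
    make_intensity_rows("P", i * 10, i * 10 + 5, "A",
                        sprintf("S%d_%d", i, 1:8),
                        rep(c("PKD1", "normal"), each = 4),
                        2^rnorm(8, 10, 0.5))
  })
  plain <- differential_peptides(rows)
  expect_false("p_adjusted" %in% names(plain))
  adj <- differential_peptides(rows, adjust = "BH")
  expect_equal(adj$p_adjusted, p.adjust(adj$p_value, "BH"))
})

test_that("zero intensities are censored, not imputed", {
  tab <- make_intensity_rows("P", 1, 9, "A", sprintf("S%d", 1:6),
                             rep(c("PKD1", "normal"), each = 3),
                             c(0, 8, 8, 2, 2, 2))
  res <- differential_peptides(tab)
  expect_equal(res$n_case, 2L)  # the zero dropped
  expect_equal(res$log2_ratio, 2)
})

test_that("slice consistency is perfect on generator output and detects misplacement", {
  tab <- simulate_dataset(pcc_preset("pc1_fig1", seed = 5))
  gt <- attr(tab, "ground_truth")
  sc <- slice_consistency(tab, gt$fragments)
  expect_equal(sc$summary$fraction_consistent, 1.0)

  moved <- tab
  moved$slice[1] <- "J"  # two or more windows below any containing fragment
  moved <- dplyr::distinct(moved)
  sc2 <- slice_consistency(moved, gt$fragments)
  expect_lt(sc2$summary$fraction_consistent, 1.0)

  expect_warning(slice_consistency(tab, gt$fragments[0, ]), "no fragment model")
})
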
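# Positional reporting, plotting, broom-style methods and the end-to-end
# pipeline driver.

#' Positional ratio report
#'
#' One point per peptide-slice key passing the differential threshold:
#' peptide start position, cohort log2 intensity ratio, total ion current,
#' gel slice and p-value — the table behind a start-position versus
#' log2-ratio scatter with point area scaling with intensity and colour
#' indicating the slice.
#'
#' @param differential result of [differential_peptides()].
#' @param table the intensity tibble the differential was computed from
#'   (unused beyond validation; the differential carries the intensities).
#' @return tibble of class `pcc_positional_report` with columns
#'   `protein_id`, `start`, `log2_ratio`, `total_intensity`, `slice`,
#'   `p_value`.  Empty (with full header) when nothing passes.
#' @export
positional_report <- function(differential, table = NULL) {
  pts <- differential[differential$passes_threshold, , drop = FALSE]
  out <- tibble::tibble(
    protein_id = pts$protein_id,
    start = pts$start,
    log2_ratio = pts$log2_ratio,
    total_intensity = pts$total_intensity,
    slice = pts$slice,
    p_value = pts$p_value
  )
  class(out) <- c("pcc_positional_report", class(out))
  out
}

#' Plot a positional ratio report
#'
#' Start position on the y axis against the case/control log2 intensity
#' ratio on the x axis, point area scaling with total ion current, colour
#' by gel slice, faceted by protein.
#'
#' @param points a `pcc_positional_report` (or compatible tibble).
#' @return a ggplot object.
#' @export
plot_positional_ratio <- function(points) {
  ggplot2::ggplot(points, ggplot2::aes(
    x = .data$log2_ratio, y = .data$start,
    size = .data$total_intensity, colour = .data$slice
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_size_area(max_size = 6, guide = "none") +
    ggplot2::facet_wrap(ggplot2::vars(.data$protein_id), scales = "free_y") +
    ggplot2::labs(x = "log2 intensity ratio (case/control)",
                  y = "peptide start position (aa)", colour = "gel slice") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.pcc_differential <- function(object, ...) {
  plot_positional_ratio(positional_report(object))
}

#' @exportS3Method ggplot2::autoplot
autoplot.pcc_cleavage_calls <- function(object, ...) {
  profile <- attr(object, "profile")
  if (is.null(profile)) stop("no score profile attached", call. = FALSE)
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$candidate, y = .data$score)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "candidate boundary (aa)",
                  y = "separation score (JSD x min side support)") +
    ggplot2::theme_minimal()
  if (nrow(object) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = object$position,
                                 linetype = 2, colour = "red")
  }
  p
}

#' @exportS3Method generics::tidy
tidy.pcc_differential <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' @exportS3Method generics::glance
glance.pcc_differential <- function(x, ...) {
  tibble::tibble(
    n_keys = nrow(x),
    n_tested = sum(!is.na(x$p_value)),
    n_passing = sum(x$passes_threshold),
    n_decreased = sum(x$passes_threshold & x$log2_ratio < 0),
    n_increased = sum(x$passes_threshold & x$log2_ratio > 0),
    alpha = attr(x, "alpha")
  )
}

#' @exportS3Method generics::tidy
tidy.pcc_cleavage_calls <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' @exportS3Method generics::glance
glance.pcc_cleavage_calls <- function(x, ...) {
  tibble::tibble(
    n_calls = nrow(x),
    top_position = if (nrow(x) > 0) x$position[1] else NA_real_,
    top_score = if (nrow(x) > 0) x$score[1] else NA_real_
  )
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) an intensity table, runs the two-cohort
#' differential analysis, writes the positional report, and infers cleavage
#' positions per protein.  All outputs are plain delimited text plus a JSON
#' manifest (inputs, seed, parameters, output checksums); a fixed seed
#' reproduces every file byte for byte.
#'
#' @param config a preset name (see [pcc_preset()]), a
#'   `pcc_synthetic_config`, or the path to a YAML file with keys `preset`,
#'   optional `seed`, `alpha`, and/or `table` (path to an intensity table
#'   to analyse instead of simulating).
#' @param out_dir output directory (created if missing).
#' @param seed simulation seed; overrides the config's.
#' @param alpha differential significance level (default 0.01).
#' @param format `"tsv"` (default) or `"csv"`.
#' @return invisibly, a named list of output paths.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, alpha = 0.01,
                         format = c("tsv", "csv")) {
  format <- match.arg(format)
  ext <- paste0(".", format)
  params <- list()
  table_path_in <- NULL
  if (is.character(config) && length(config) == 1 && file.exists(config) &&
      grepl("\\.ya?ml$", config)) {
    cfg_file <- yaml::read_yaml(config)
    if (!is.null(cfg_file$seed) && is.null(seed)) seed <- cfg_file$seed
    if (!is.null(cfg_file$alpha)) alpha <- cfg_file$alpha
    if (!is.null(cfg_file$table)) {
      table_path_in <- cfg_file$table
    } else if (!is.null(cfg_file$preset)) {
      config <- cfg_file$preset
    } else {
      stop("pipeline config ", config, " needs a 'preset' or 'table' entry",
           call. = FALSE)
    }
  } else if (is.character(config) && length(config) == 1 &&
             grepl("\\.ya?ml$", config)) {
    stop("pipeline config file not found: ", config, call. = FALSE)
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  if (!is.null(table_path_in)) {
    if (!file.exists(table_path_in)) {
      stop("input intensity table not found: ", table_path_in, call. = FALSE)
    }
    table <- read_intensity_table(table_path_in)
    params$input_table <- table_path_in
    gt <- NULL
  } else {
    if (is.character(config)) {
      config <- pcc_preset(config, seed = if (is.null(seed)) 1 else seed)
    } else if (!is.null(seed)) {
      config$seed <- as.integer(seed)
    }
    stopifnot(inherits(config, "pcc_synthetic_config"))
    params$preset <- config$preset
    params$seed <- config$seed
    table <- simulate_dataset(config)
    gt <- attr(table, "ground_truth")
    paths$table <- file.path(out_dir, paste0("intensity_table", ext))
    write_intensity_table(table, paths$table)
    paths$ground_truth <- file.path(out_dir, "ground_truth.yaml")
    yaml::write_yaml(list(
      preset = config$preset, seed = config$seed,
      planted = config$planted,
      noise_sd_log2 = config$noise_sd_log2,
      detect_prob = config$detect_prob,
      cohort_fc = as.list(config$cohort_fc)
    ), paths$ground_truth)
  }
  params$alpha <- alpha

  write_out <- function(tbl, name) {
    path <- file.path(out_dir, paste0(name, ext))
    if (format == "csv") readr::write_csv(tibble::as_tibble(tbl), path, progress = FALSE)
    else readr::write_tsv(tibble::as_tibble(tbl), path, progress = FALSE)
    path
  }

  differential <- differential_peptides(table, alpha = alpha)
  paths$differential <- write_out(tidy(differential), "differential")
  paths$positional <- write_out(positional_report(differential), "positional_report")

  calls <- purrr::map_dfr(unique(table$protein_id), function(pid) {
    res <- tryCatch(
      suppressWarnings(infer_cleavage_positions(table, pid)),
      error = function(e) NULL
    )
    if (is.null(res)) NULL else tibble::as_tibble(res)
  })
  paths$cleavage_calls <- write_out(calls, "cleavage_calls")

  manifest <- list(
    package = "pccleave",
    version = as.character(utils::packageVersion("pccleave")),
    parameters = params,
    outputs = purrr::map(paths, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
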
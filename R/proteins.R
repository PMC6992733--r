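# Protein sequences, feature annotations and sequon scanning.
#
# All coordinates in this package are 1-based and inclusive.  A cleavage
# site at position p means the peptide bond between residues p and p + 1 is
# hydrolysed: the N-terminal product is [1..p] and the C-terminal product is
# [p+1..length].

.AA_CANONICAL <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

.FEATURE_KINDS <- c("TM", "signal_peptide", "coiled_coil", "sequon",
                    "annotated_cleavage", "domain")

.GLYCAN_STATES <- c("endoH_sensitive", "mature")

#' Validate an amino-acid sequence
#'
#' Checks that a sequence is non-empty and contains only the twenty
#' canonical residues.  Ambiguity codes (B, J, O, U, X, Z) are rejected with
#' an error naming the first offending position.
#'
#' @param sequence character vector of amino-acid sequences.
#' @param what label used in error messages.
#' @return the uppercased sequence, invisibly usable downstream.
#' @export
validate_sequence <- function(sequence, what = "sequence") {
  if (length(sequence) == 0 || any(is.na(sequence)) || any(nchar(sequence) == 0)) {
    stop(what, " must be a non-empty amino-acid string", call. = FALSE)
  }
  sequence <- toupper(sequence)
  for (i in seq_along(sequence)) {
    res <- strsplit(sequence[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!res %in% .AA_CANONICAL)
    if (length(bad) > 0) {
      stop(sprintf(
        "%s %d contains non-canonical residue '%s' at position %d",
        what, i, res[bad[1]], bad[1]
      ), call. = FALSE)
    }
  }
  sequence
}

#' Construct a protein record table
#'
#' The protein table is the coordinate frame for every downstream
#' computation: one row per protein with its identifier, free-text name,
#' validated sequence and residue count.
#'
#' @param id character vector of accession-like identifiers.
#' @param sequence character vector of amino-acid sequences (canonical
#'   residues only).
#' @param name optional free-text names; defaults to `id`.
#' @return a tibble with columns `id`, `name`, `sequence`, `length`.
#' @export
protein_records <- function(id, sequence, name = id) {
  if (length(id) != length(sequence)) {
    stop("id and sequence must have the same length", call. = FALSE)
  }
  if (anyDuplicated(id)) stop("duplicated protein ids", call. = FALSE)
  sequence <- unname(validate_sequence(sequence, what = "protein"))
  tibble::tibble(
    id = as.character(id),
    name = as.character(name),
    sequence = sequence,
    length = nchar(sequence)
  )
}

#' Read protein sequences from a FASTA file
#'
#' Reads a (multi-record) FASTA file into a protein record table.  The
#' description line is split at the first whitespace into `id` and `name`.
#' Sequences are uppercased and validated against the canonical alphabet.
#'
#' @param path path to a FASTA file.
#' @return a tibble as returned by [protein_records()].
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) {
      stop("malformed FASTA in ", path, ": ", conditionMessage(e), call. = FALSE)
    }
  )
  if (length(set) == 0) stop("FASTA file ", path, " contains no records", call. = FALSE)
  desc <- names(set)
  id <- sub("\\s.*$", "", desc)
  name <- ifelse(grepl("\\s", desc), sub("^\\S+\\s+", "", desc), id)
  protein_records(id = id, sequence = as.character(set), name = name)
}

#' Write protein records to FASTA
#'
#' @param proteins protein record table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  lines <- unlist(purrr::map2(proteins$id, proteins$sequence, function(id, seq) {
    c(paste0(">", id), seq)
  }))
  writeLines(lines, path)
  invisible(path)
}

.validate_ranges <- function(tbl, proteins, what) {
  lens <- stats::setNames(proteins$length, proteins$id)
  unknown <- setdiff(unique(tbl$protein_id), proteins$id)
  if (length(unknown) > 0) {
    stop(what, " references unknown protein id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  bad <- tbl$start < 1 | tbl$end < tbl$start | tbl$end > lens[tbl$protein_id]
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "%s out of range for %s: [%d..%d] (protein length %d)",
      what, tbl$protein_id[i], tbl$start[i], tbl$end[i], lens[[tbl$protein_id[i]]]
    ), call. = FALSE)
  }
  invisible(tbl)
}

#' Validate a feature table against protein records
#'
#' Features are rows of `protein_id`, `kind`, `start`, `end`, `label` with
#' 1-based inclusive coordinates.  Transmembrane (TM) features must not
#' overlap within a protein.
#'
#' @param features feature tibble.
#' @param proteins protein record table.
#' @return the validated feature tibble (columns coerced, sorted by protein
#'   and start).
#' @export
validate_features <- function(features, proteins) {
  if (nrow(features) == 0) {
    return(tibble::tibble(protein_id = character(), kind = character(),
                          start = integer(), end = integer(), label = character()))
  }
  features <- tibble::as_tibble(features)
  if (!all(c("protein_id", "kind", "start", "end") %in% names(features))) {
    stop("features need columns protein_id, kind, start, end", call. = FALSE)
  }
  if (!"label" %in% names(features)) features$label <- features$kind
  bad_kind <- setdiff(unique(features$kind), .FEATURE_KINDS)
  if (length(bad_kind) > 0) {
    stop("unknown feature kind(s): ", paste(bad_kind, collapse = ", "), call. = FALSE)
  }
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  .validate_ranges(features, proteins, "feature")
  tm <- features[features$kind == "TM", , drop = FALSE]
  if (nrow(tm) > 1) {
    for (pid in unique(tm$protein_id)) {
      x <- tm[tm$protein_id == pid, ]
      x <- x[order(x$start), ]
      if (any(x$start[-1] <= x$end[-nrow(x)])) {
        stop("overlapping TM features in protein ", pid, call. = FALSE)
      }
    }
  }
  dplyr::arrange(features, .data$protein_id, .data$start)
}

#' Load protein features, cleavage sites and glycans from a config file
#'
#' The structured config is YAML of the form
#' ```yaml
#' proteins:
#'   P1:
#'     features:
#'       - {kind: TM, start: 10, end: 30, label: TM1}
#'     cleavage_sites:
#'       - {position: 50, label: GPS}
#'     glycans:
#'       - {position: 70, state: mature, mass_kDa: 5}
#' ```
#' Coordinates are validated against the supplied protein records: features
#' must lie inside the protein, cleavage positions must satisfy
#' `1 <= position < length`, and a glycan position must be an asparagine.
#'
#' @param path path to the YAML config.
#' @param proteins protein record table the config refers to.
#' @return a list with tibbles `features`, `cleavage_sites`, `glycans`.
#' @export
read_feature_config <- function(path, proteins) {
  if (!file.exists(path)) stop("feature config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$proteins)) stop("feature config has no 'proteins' section", call. = FALSE)
  feature_config(cfg$proteins, proteins)
}

#' Build a validated feature set from a nested list
#'
#' List equivalent of [read_feature_config()]: `config` is a named list
#' keyed by protein id, each element holding optional `features`,
#' `cleavage_sites` and `glycans` lists.
#'
#' @param config named list, one element per protein.
#' @param proteins protein record table.
#' @return a list with tibbles `features`, `cleavage_sites`, `glycans`.
#' @export
feature_config <- function(config, proteins) {
  gather <- function(field, cols) {
    rows <- purrr::imap(config, function(entry, pid) {
      items <- entry[[field]]
      if (is.null(items) || length(items) == 0) return(NULL)
      tb <- dplyr::bind_rows(purrr::map(items, tibble::as_tibble))
      tb$protein_id <- pid
      tb
    })
    out <- dplyr::bind_rows(rows)
    if (nrow(out) == 0) {
      out <- tibble::as_tibble(stats::setNames(
        purrr::map(cols, function(cl) if (cl %in% c("protein_id", "kind", "label", "state")) character() else numeric()),
        cols
      ))
    }
    dplyr::select(out, dplyr::all_of(cols))
  }

  features <- validate_features(
    gather("features", c("protein_id", "kind", "start", "end", "label")),
    proteins
  )

  sites <- gather("cleavage_sites", c("protein_id", "position", "label"))
  sites$position <- as.integer(sites$position)
  if (nrow(sites) > 0) {
    lens <- stats::setNames(proteins$length, proteins$id)
    unknown <- setdiff(unique(sites$protein_id), proteins$id)
    if (length(unknown) > 0) {
      stop("cleavage site references unknown protein id(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    bad <- sites$position < 1 | sites$position >= lens[sites$protein_id]
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("cleavage position %d invalid for %s (needs 1 <= p < length)",
                   sites$position[i], sites$protein_id[i]), call. = FALSE)
    }
  }

  glycans <- gather("glycans", c("protein_id", "position", "state", "mass_kDa"))
  glycans$position <- as.integer(glycans$position)
  if (nrow(glycans) > 0) {
    bad_state <- setdiff(unique(glycans$state), .GLYCAN_STATES)
    if (length(bad_state) > 0) {
      stop("unknown glycan state(s): ", paste(bad_state, collapse = ", "), call. = FALSE)
    }
    if (any(glycans$mass_kDa < 0)) stop("glycan mass_kDa must be >= 0", call. = FALSE)
    gl <- glycans
    gl$start <- gl$position
    gl$end <- gl$position
    .validate_ranges(gl, proteins, "glycan")
    seqs <- stats::setNames(proteins$sequence, proteins$id)
    res <- substr(seqs[glycans$protein_id], glycans$position, glycans$position)
    if (any(res != "N")) {
      i <- which(res != "N")[1]
      stop(sprintf("glycan at %s:%d is on residue '%s', not an asparagine",
                   glycans$protein_id[i], glycans$position[i], res[i]), call. = FALSE)
    }
  }

  list(features = features, cleavage_sites = sites, glycans = glycans)
}

#' Serialize a feature set back to YAML
#'
#' Inverse of [read_feature_config()]; `read(write(x)) == x` up to row
#' order.
#'
#' @param feature_set list with `features`, `cleavage_sites`, `glycans`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_config <- function(feature_set, path) {
  pids <- sort(unique(c(feature_set$features$protein_id,
                        feature_set$cleavage_sites$protein_id,
                        feature_set$glycans$protein_id)))
  as_items <- function(tbl) {
    purrr::transpose(as.list(dplyr::select(tbl, -"protein_id")))
  }
  out <- list(proteins = stats::setNames(purrr::map(pids, function(pid) {
    entry <- list()
    f <- feature_set$features[feature_set$features$protein_id == pid, ]
    s <- feature_set$cleavage_sites[feature_set$cleavage_sites$protein_id == pid, ]
    g <- feature_set$glycans[feature_set$glycans$protein_id == pid, ]
    if (nrow(f) > 0) entry$features <- as_items(f)
    if (nrow(s) > 0) entry$cleavage_sites <- as_items(s)
    if (nrow(g) > 0) entry$glycans <- as_items(g)
    entry
  }), pids))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Scan protein sequences for N-glycosylation sequons
#'
#' Finds every match of the sequon motif N-X-\[S/T/C\] and returns the
#' 1-based position of the asparagine.  By default X may be any residue
#' except proline (the standard biochemical rule); set
#' `exclude_proline = FALSE` to allow any X.  Matches may overlap.
#'
#' @param proteins protein record table (or a bare character vector of
#'   sequences, in which case ids `seq1..seqN` are invented).
#' @param region optional `c(start, end)` residue range to restrict the scan
#'   (the asparagine must lie inside the range; the X/\[S/T/C\] positions may
#'   extend past its end).
#' @param exclude_proline logical; disallow proline at X (default `TRUE`).
#' @return tibble with columns `protein_id`, `position`, `motif`.
#' @export
find_sequons <- function(proteins, region = NULL, exclude_proline = TRUE) {
  if (is.character(proteins)) {
    proteins <- protein_records(paste0("seq", seq_along(proteins)), proteins)
  }
  x_class <- if (exclude_proline) "[^P]" else "."
  pattern <- paste0("N(?=", x_class, "[STC])")
  purrr::pmap_dfr(list(proteins$id, proteins$sequence, proteins$length),
                  function(pid, seq, len) {
    from <- 1L
    to <- len
    if (!is.null(region)) {
      if (region[1] < 1 || region[2] > len || region[1] > region[2]) {
        stop("region out of range for protein ", pid, call. = FALSE)
      }
      from <- as.integer(region[1])
      to <- as.integer(region[2])
    }
    hits <- gregexpr(pattern, seq, perl = TRUE)[[1]]
    if (hits[1] == -1) {
      return(tibble::tibble(protein_id = character(), position = integer(),
                            motif = character()))
    }
    pos <- as.integer(hits)
    pos <- pos[pos >= from & pos <= to & pos + 2L <= len]
    tibble::tibble(
      protein_id = pid,
      position = pos,
      motif = substr(seq, pos, pos + 2L)
    )
  })
}
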
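#' Write / read a raw curve as TSV
#'
#' Plain-text dialect: `#`-prefixed `key: value` metadata header lines, then
#' a tab-separated table with header `time_s`, `z_um`, `force_uN` (any column
#' order, header-driven). Numbers are written with 9 significant digits, so a
#' write/read round trip is lossless at that precision.
#'
#' @param curve A `raw_curve`.
#' @param path Output file path.
#' @return `write_curve()`: the path, invisibly. `read_curve()`: a
#'   `raw_curve`.
#' @export
write_curve <- function(curve, path) {
  meta <- attr(curve, "meta") %||% list()
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (key in names(meta)) {
    writeLines(sprintf("# %s: %s", key, format(meta[[key]], digits = 12)), con)
  }
  writeLines("time_s\tz_um\tforce_uN", con)
  writeLines(
    sprintf(
      "%.9g\t%.9g\t%.9g",
      curve$time_s, curve$z_um, curve$force_uN
    ),
    con
  )
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- grepl("^#", lines)
  n_meta <- match(FALSE, is_meta) - 1L
  if (is.na(n_meta)) n_meta <- length(lines)
  meta <- list()
  if (n_meta > 0) {
    for (i in seq_len(n_meta)) {
      m <- regmatches(
        lines[i],
        regexec("^#\\s*([^:]+):\\s*(.*)$", lines[i])
      )[[1]]
      if (length(m) != 3) {
        abort(sprintf("%s: malformed metadata at line %d", basename(path), i))
      }
      key <- trimws(m[2])
      val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  if (length(lines) <= n_meta) {
    abort(sprintf("%s: no data table after line %d", basename(path), n_meta))
  }
  hdr <- strsplit(lines[n_meta + 1L], "\t", fixed = TRUE)[[1]]
  need <- c("time_s", "z_um", "force_uN")
  if (!all(need %in% hdr)) {
    abort(sprintf(
      "%s: line %d: missing column(s) %s", basename(path), n_meta + 1L,
      paste(setdiff(need, hdr), collapse = ", ")
    ))
  }
  body <- lines[-seq_len(n_meta + 1L)]
  if (length(body) < 2) {
    abort(sprintf("%s: truncated file: no data after line %d", basename(path), n_meta + 1L))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != length(hdr))
  if (length(bad)) {
    abort(sprintf(
      "%s: line %d: expected %d fields, got %d",
      basename(path), n_meta + 1L + bad[1], length(hdr), lengths(parts)[bad[1]]
    ))
  }
  mat <- matrix(
    suppressWarnings(as.numeric(unlist(parts))),
    ncol = length(hdr), byrow = TRUE, dimnames = list(NULL, hdr)
  )
  if (anyNA(mat)) {
    bad <- which(rowSums(is.na(mat)) > 0)[1]
    abort(sprintf("%s: line %d: non-numeric value", basename(path), n_meta + 1L + bad))
  }
  tm <- mat[, "time_s"]
  if (any(diff(tm) <= 0)) {
    bad <- which(diff(tm) <= 0)[1]
    abort(sprintf("%s: line %d: time not strictly increasing", basename(path), n_meta + 2L + bad))
  }
  out <- tibble(time_s = tm, z_um = mat[, "z_um"], force_uN = mat[, "force_uN"])
  attr(out, "meta") <- meta
  class(out) <- c("raw_curve", class(out))
  out
}

#' Write / read a simulated cohort directory
#'
#' One TSV per curve plus `manifest.json` holding schema version, seed,
#' sensor, protocol, per-tube ground truth and the curve index. The manifest
#' carries a content hash of the configuration for provenance.
#'
#' @param cohort A `cfm_cohort` from [simulate_cohort()].
#' @param dir Directory (created if needed).
#' @return `write_cohort()`: `dir`, invisibly. `read_cohort()`: a
#'   `cfm_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cfm_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s.tsv", names(cohort$curves))
  for (i in seq_along(cohort$curves)) {
    write_curve(cohort$curves[[i]], file.path(dir, files[i]))
  }
  man <- cohort$manifest
  man$files <- files
  man$config_hash <- rlang::hash(man[setdiff(names(man), "config_hash")])
  jsonlite::write_json(
    man,
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) abort(sprintf("no manifest.json in %s", dir))
  man <- jsonlite::read_json(mp, simplifyVector = TRUE)
  if (!identical(man$schema_version, .schema_version)) {
    abort(sprintf(
      "manifest schema version %s not supported (expected %s)",
      man$schema_version, .schema_version
    ))
  }
  missing <- man$files[!file.exists(file.path(dir, man$files))]
  if (length(missing)) {
    abort(sprintf("curve file(s) listed in manifest but absent: %s",
      paste(missing, collapse = ", ")))
  }
  curves <- lapply(file.path(dir, man$files), read_curve)
  names(curves) <- sub("\\.tsv$", "", man$files)
  man$tubes <- as_tibble(man$tubes)
  man$curve_index <- as_tibble(man$curve_index)
  structure(list(curves = curves, manifest = man), class = "cfm_cohort")
}

#' Pipeline run configuration
#'
#' Bundles and validates every tunable of the end-to-end pipeline.
#'
#' @param window Maximum-load window fraction in (0, 1).
#' @param contact_threshold Contact-detection threshold, baseline SDs.
#' @param contact_run Consecutive above-threshold samples required.
#' @param baseline_fraction Approach fraction used for the baseline fit.
#' @param n_perm Permutations for the group comparison.
#' @param tolerance Stiffness-matching tolerance of the inversion.
#' @param ranges A [param_ranges()] for the inversion.
#' @param seed Integer seed for the stochastic stages.
#' @return An object of class `run_config`.
#' @export
run_config <- function(window = 0.2, contact_threshold = 5, contact_run = 5,
                       baseline_fraction = 0.2, n_perm = 9999,
                       tolerance = 0.10, ranges = param_ranges(), seed = 1) {
  if (!(window > 0 && window < 1)) abort("window must be in (0, 1)")
  if (!(baseline_fraction > 0 && baseline_fraction < 0.5)) {
    abort("baseline_fraction must be in (0, 0.5)")
  }
  if (contact_threshold <= 0 || contact_run < 1) abort("invalid contact detection settings")
  if (n_perm < 999) abort("n_perm must be >= 999")
  if (!(tolerance > 0 && tolerance < 1)) abort("tolerance must be in (0, 1)")
  stopifnot(inherits(ranges, "param_ranges"))
  structure(
    list(
      window = window, contact_threshold = contact_threshold,
      contact_run = contact_run, baseline_fraction = baseline_fraction,
      n_perm = n_perm, tolerance = tolerance, ranges = ranges,
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Run the full analysis pipeline on a cohort directory
#'
#' process -> statistics -> group comparison -> modulus inversion, writing
#' `records.csv`, `stats.csv`, `comparison.json` (when two groups are
#' present), `compatible_set.csv`, `inversion.json` and `log.txt` into
#' `output_dir`. Identical inputs and configuration produce byte-identical
#' outputs. Any stage failure aborts with a stage-labelled message.
#'
#' @param input_dir Directory holding `manifest.json` and curve TSVs.
#' @param output_dir Output directory (created if needed).
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory artifacts (`records`,
#'   `stats`, `comparison`, `compatible`).
#' @export
run_pipeline <- function(input_dir, output_dir, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(file.path(input_dir, "manifest.json"))) {
    abort(sprintf("input directory %s has no manifest.json; nothing to do", input_dir))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- rlang::hash(config)

  cohort <- stage("read", read_cohort(input_dir))
  records <- stage("process", process_cohort(cohort, window = config$window))
  .write_csv(records, file.path(output_dir, "records.csv"), hash)

  stats <- stage("stats", cohort_statistics(records))
  .write_csv(stats, file.path(output_dir, "stats.csv"), hash)

  groups <- unique(records$group)
  comparison <- NULL
  if (length(groups) >= 2) {
    comparison <- stage("compare", compare_groups(
      records, groups[1], groups[2],
      n_perm = config$n_perm, seed = config$seed
    ))
    jsonlite::write_json(
      c(
        list(schema_version = .schema_version, config_hash = hash),
        unclass(tidy(comparison))
      ),
      file.path(output_dir, "comparison.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }

  k_target <- stats$mean_nm[stats$phase == "load"][1]
  compatible <- stage("invert", compatible_set(
    k_target,
    tolerance = config$tolerance, ranges = config$ranges
  ))
  .write_csv(compatible$table, file.path(output_dir, "compatible_set.csv"), hash)
  jsonlite::write_json(
    c(
      list(schema_version = .schema_version, config_hash = hash),
      unclass(glance(compatible))
    ),
    file.path(output_dir, "inversion.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  writeLines(
    c(
      sprintf("schema_version: %s", .schema_version),
      sprintf("config_hash: %s", hash),
      sprintf("seed: %d", config$seed),
      sprintf("curves: %d", length(cohort$curves)),
      sprintf("groups: %s", paste(groups, collapse = ", ")),
      sprintf("k_target: %.9g", k_target)
    ),
    file.path(output_dir, "log.txt")
  )
  invisible(list(
    records = records, stats = stats,
    comparison = comparison, compatible = compatible
  ))
}

# CSV with provenance header; deterministic formatting
.write_csv <- function(df, path, hash) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# schema_version: %s", .schema_version), con)
  writeLines(sprintf("# config_hash: %s", hash), con)
  fmt <- vapply(df, function(col) is.numeric(col), logical(1))
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df)) {
    cols <- lapply(seq_along(df), function(j) {
      if (fmt[j]) sprintf("%.9g", df[[j]]) else as.character(df[[j]])
    })
    writeLines(do.call(paste, c(cols, sep = ",")), con)
  }
  invisible(path)
}
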
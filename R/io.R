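#' Write / read a waveform record as CSV or TSV
#'
#' The on-disk waveform format is a plain delimited table with columns
#' `time_s`, `abp_mmHg`, `cbfv_cms`, `co2_mmHg` (extension `.tsv` selects
#' tab delimiting). On read, the sampling rate is inferred from the time
#' column and checked uniform within 1%; non-monotone time or a missing
#' channel is an error.
#'
#' @param record A `waveform_record` (see [simulate_waveforms()]).
#' @param path File path; written atomically (write-then-rename).
#' @return `write_waveforms()` the path, invisibly; `read_waveforms()` a
#'   `waveform_record` tibble with the `fs` attribute set.
#' @export
write_waveforms <- function(record, path) {
  atomic_write(path, function(tmp) {
    write_delim_precise(as_tibble(record)[, c("time_s", "abp_mmHg",
                                              "cbfv_cms", "co2_mmHg")],
                        tmp, tsv = grepl("\\.tsv$", path))
  })
  invisible(path)
}

# internal: delimited write with doubles rendered at 17 significant digits
# so a read-back is bit-identical to the in-memory values
write_delim_precise <- function(df, path, tsv = FALSE) {
  for (cl in names(df)) {
    if (is.double(df[[cl]])) {
      df[[cl]] <- ifelse(is.na(df[[cl]]), NA_character_,
                         sprintf("%.17g", df[[cl]]))
    }
  }
  if (tsv) readr::write_tsv(df, path) else readr::write_csv(df, path)
}

#' @rdname write_waveforms
#' @export
read_waveforms <- function(path) {
  if (!file.exists(path)) {
    dvr_abort(paste0("File not found: ", path), "dvr_missing_file")
  }
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  # read numerics as text and convert with base R's correctly-rounded
  # parser, so values written at full precision round-trip bit-identically
  d <- reader(path, show_col_types = FALSE, progress = FALSE,
              col_types = readr::cols(.default = readr::col_character()))
  d <- as_tibble(lapply(d, function(cl) {
    num <- suppressWarnings(as.numeric(cl))
    if (all(is.na(num) == is.na(cl))) num else cl
  }))
  required <- c("time_s", "abp_mmHg", "cbfv_cms", "co2_mmHg")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols) > 0L) {
    dvr_abort(paste0("Missing channel column(s): ",
                     paste(missing_cols, collapse = ", ")), "dvr_bad_table")
  }
  if (anyNA(d[required])) {
    dvr_abort("Non-finite samples in the waveform file.", "dvr_bad_samples")
  }
  dt <- diff(d$time_s)
  if (any(dt <= 0)) {
    dvr_abort("Time column is not strictly increasing.", "dvr_bad_time")
  }
  if (max(abs(dt - median(dt))) > 0.01 * median(dt)) {
    dvr_abort("Sampling is not uniform within 1%.", "dvr_bad_time")
  }
  fs <- 1 / median(dt)
  structure(d, fs = fs, class = c("waveform_record", class(d)))
}

#' Read a cohort subject table from CSV
#'
#' Requires columns `id`, `group`, `age`, `gender`, `education`; any
#' further numeric columns are treated as markers/scores. Empty cells
#' become `NA` and are handled downstream by pairwise-complete deletion.
#'
#' @param path CSV file path.
#' @param groups Admissible group labels.
#' @return A `subject_table` tibble; `attr(, "missingness")` is a logical
#'   tibble marking missing marker cells.
#' @export
read_subject_table <- function(path, groups = c("CS", "MP")) {
  if (!file.exists(path)) {
    dvr_abort(paste0("File not found: ", path), "dvr_missing_file")
  }
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("id", "group", "age", "gender", "education")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols) > 0L) {
    dvr_abort(paste0("Missing required column(s): ",
                     paste(missing_cols, collapse = ", ")), "dvr_bad_table")
  }
  bad <- setdiff(unique(d$group), groups)
  if (length(bad) > 0L) {
    dvr_abort(paste0("Unknown group label(s): ", paste(bad, collapse = ", ")),
              "dvr_bad_group")
  }
  if (anyDuplicated(d$id)) {
    dvr_abort("Duplicate subject ids.", "dvr_duplicate_id")
  }
  markers <- setdiff(names(d)[vapply(d, is.numeric, logical(1))],
                     c("age", "gender", "education"))
  miss <- as_tibble(lapply(d[markers], is.na))
  structure(d, missingness = miss,
            class = c("subject_table", class(d)))
}

#' Write an analysis report (tables as CSV, provenance as JSON)
#'
#' Every tibble in `results` is written as `<name>.csv`; scalars and the
#' run provenance (config, seed, a hash of both, package version) go into
#' `report.json`. All writes are atomic.
#'
#' @param results Named list of tibbles and/or scalars.
#' @param dir Output directory (created if needed).
#' @param config Optional [dvr_config()] to embed.
#' @param seed Optional seed to embed.
#' @return Invisible character vector of the files written.
#' @export
write_report <- function(results, dir, config = NULL, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  scalars <- list()
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      p <- file.path(dir, paste0(nm, ".csv"))
      atomic_write(p, function(tmp) write_delim_precise(as_tibble(x), tmp))
      written <- c(written, p)
    } else {
      scalars[[nm]] <- x
    }
  }
  provenance <- list(
    package = "dvrkit",
    version = as.character(utils::packageVersion("dvrkit")),
    seed = seed,
    config = if (!is.null(config)) unclass(config),
    config_hash = rlang::hash(list(config = config, seed = seed)))
  p <- file.path(dir, "report.json")
  atomic_write(p, function(tmp) {
    jsonlite::write_json(list(provenance = provenance, results = scalars),
                         tmp, auto_unbox = TRUE, digits = NA, null = "null")
  })
  invisible(c(written, p))
}

#' Serialize a fitted two-input model to JSON (and back)
#'
#' @param model A `two_input_model`.
#' @param path JSON file path.
#' @return `write_model()` the path invisibly; `read_model()` the
#'   reconstructed `two_input_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "two_input_model"))
  x <- list(alpha_p = model$basis_p$alpha, L_p = model$basis_p$L,
            M_p = model$basis_p$M,
            alpha_c = model$basis_c$alpha, L_c = model$basis_c$L,
            M_c = model$basis_c$M,
            a_p = model$a_p, a_c = model$a_c,
            intercept = model$intercept, dt = model$dt,
            fit_nmse = model$fit_nmse,
            baselines = as.list(model$baselines))
  atomic_write(path, function(tmp) {
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  })
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(basis_p = laguerre_basis(x$alpha_p, x$L_p, x$M_p),
         basis_c = laguerre_basis(x$alpha_c, x$L_c, x$M_c),
         a_p = as.numeric(x$a_p), a_c = as.numeric(x$a_c),
         intercept = x$intercept, dt = x$dt, fit_nmse = x$fit_nmse,
         baselines = unlist(x$baselines)),
    class = "two_input_model")
}
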
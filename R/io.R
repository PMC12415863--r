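record_columns <- c("species", "concentration_uL_per_L", "IT_s", "RT_s",
                    "WBC", "RBC", "HGB", "HCT")

check_records <- function(records) {
  if (!is.data.frame(records)) {
    stop("records must be a data frame", call. = FALSE)
  }
  missing <- setdiff(record_columns, names(records))
  if (length(missing)) {
    stop("records missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read / write per-fish record files
#'
#' The package's record CSV dialect: UTF-8, "." decimal, unit-bearing header
#' \code{species,concentration_uL_per_L,IT_s,RT_s,WBC,RBC,HGB,HCT}, one row
#' per fish. Reading validates the header and every numeric cell, naming the
#' offending column (and row) on failure; writing and re-reading is lossless
#' and preserves row order.
#'
#' @param path CSV file path.
#' @return \code{read_records}: a [tibble::tibble()] of records.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) {
    stop("records file not found: ", path, call. = FALSE)
  }
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  fileEncoding = "UTF-8")
  missing <- setdiff(record_columns, names(raw))
  if (length(missing)) {
    stop("parse error: missing column(s) ", paste(missing, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  raw <- raw[, record_columns]
  for (col in setdiff(record_columns, "species")) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals))
    if (length(bad)) {
      stop("parse error: non-numeric value '", raw[[col]][bad[1]],
           "' at row ", bad[1], ", column ", col, call. = FALSE)
    }
    raw[[col]] <- vals
  }
  tibble::as_tibble(raw)
}

#' @rdname read_records
#' @param records A records table (see [generate_dataset()]).
#' @export
write_records <- function(records, path) {
  check_records(records)
  write.csv(records[, record_columns], path, row.names = FALSE,
            fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Read and validate a run configuration
#'
#' Run configurations are YAML documents controlling a full analysis run:
#' species list, master seed, generator overrides (\code{noise_cv},
#' \code{n_per_dose}), trainer defaults, search-grid bounds, dose constraints
#' and the output directory. Every omitted field is filled with the package
#' default, so the returned effective configuration is fully explicit and can
#' be logged alongside results for reproducibility.
#'
#' @param path Path to a YAML file, or \code{NULL} for pure defaults.
#' @return A named list: \code{species}, \code{seed}, \code{noise_cv},
#'   \code{n_per_dose}, \code{grid_H}, \code{trainer_defaults},
#'   \code{it_max_s}, \code{rt_max_s}, \code{output_dir}.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (!is.list(cfg)) {
    stop("run config must be a YAML mapping", call. = FALSE)
  }
  defaults <- list(
    species = species_levels,
    seed = 1L,
    noise_cv = 0.03,
    n_per_dose = 10L,
    grid_H = 4:10,
    trainer_defaults = list(),
    it_max_s = 180,
    rt_max_s = 300,
    output_dir = "results"
  )
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    stop("unknown run-config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  eff <- utils::modifyList(defaults, cfg)
  if (!all(eff$species %in% species_levels)) {
    stop("run config: unknown species ",
         paste(setdiff(eff$species, species_levels), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(eff$noise_cv >= 0, eff$n_per_dose >= 1,
            eff$it_max_s > 0, eff$rt_max_s > 0)
  eff$seed <- as.integer(eff$seed)
  eff
}
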
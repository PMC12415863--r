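#' @importFrom utils read.csv write.csv
NULL

species_levels <- c("common_carp", "danube_sturgeon", "rainbow_trout")
endpoint_levels <- c("IT", "RT", "WBC", "RBC", "HGB", "HCT")

# concentration ranges (uL/L) actually tested per species
species_dose_range <- list(
  common_carp = c(800, 1400),
  danube_sturgeon = c(500, 1000),
  rainbow_trout = c(400, 800)
)

#' Load the packaged model zoo
#'
#' The zoo holds the eighteen published trained networks (three species by
#' six endpoints: induction time IT, recovery time RT, and the hematological
#' endpoints WBC, RBC, HGB, HCT), transcribed digit-for-digit from the printed
#' weight tables. Transcription is deliberately uncorrected: blocks whose
#' printed label, row count or values conflict with the narrative text carry
#' \code{caveats} instead of silent repairs (see [validate_entry()]).
#'
#' The printed tables do not state whether the weights expect raw
#' concentrations in uL/L or 0-1 normalized inputs; the very large printed
#' biases are inconsistent with normalized inputs, so every entry records
#' \code{input_scale = "unverified"} and [zoo_predict()] defaults to raw uL/L
#' while surfacing the tag.
#'
#' @param logsig_dialect Which logistic dialect to use for entries whose
#'   hidden layer is printed as "logsig": \code{"paper"} (the printed
#'   two-scaled form \eqn{2/(1+e^{-x})}, the default) or \code{"standard"}
#'   (canonical \eqn{1/(1+e^{-x})}).
#' @return A named list of 18 \code{zoo_entry} objects, keyed
#'   \code{"species.endpoint"}. Each entry has fields \code{species},
#'   \code{endpoint}, \code{architecture}, \code{trainer_name}, \code{params}
#'   (an [ann_network()]), \code{input_scale} and \code{caveats}.
#' @export
load_zoo <- function(logsig_dialect = c("paper", "standard")) {
  logsig_dialect <- match.arg(logsig_dialect)
  wfile <- system.file("extdata", "zoo_weights.csv", package = "anesdose")
  mfile <- system.file("extdata", "zoo_meta.csv", package = "anesdose")
  if (!nzchar(wfile) || !nzchar(mfile)) {
    stop("packaged zoo data is missing", call. = FALSE)
  }
  weights <- read.csv(wfile, colClasses = "character")
  meta <- read.csv(mfile, colClasses = "character")
  needed_w <- c("species", "endpoint", "i", "w1", "theta_i", "lw")
  if (!identical(names(weights), needed_w) || nrow(meta) != 18L) {
    stop("packaged zoo data is corrupted", call. = FALSE)
  }
  entries <- lapply(seq_len(nrow(meta)), function(k) {
    m <- meta[k, ]
    block <- weights[weights$species == m$species &
                       weights$endpoint == m$endpoint, , drop = FALSE]
    vals <- vapply(c(block$w1, block$theta_i, block$lw, m$output_bias),
                   as.numeric, numeric(1))
    if (nrow(block) == 0L || anyNA(vals)) {
      stop("packaged zoo data is corrupted for ", m$species, " ", m$endpoint,
           call. = FALSE)
    }
    hidden <- switch(m$hidden_activation,
      logsig = if (logsig_dialect == "paper") "logsig_paper" else "logsig_standard",
      m$hidden_activation
    )
    H <- nrow(block)
    caveats <- if (nzchar(m$caveats)) strsplit(m$caveats, "|", fixed = TRUE)[[1]]
               else character(0)
    structure(
      list(
        species = m$species,
        endpoint = m$endpoint,
        architecture = m$architecture,
        trainer_name = m$trainer_name,
        params = ann_network(
          input_weights = as.numeric(block$w1),
          hidden_biases = as.numeric(block$theta_i),
          output_weights = as.numeric(block$lw),
          output_bias = as.numeric(m$output_bias),
          hidden_activation = hidden,
          output_activation = m$output_activation
        ),
        neuron_index = as.integer(block$i),
        input_scale = "unverified",
        caveats = caveats
      ),
      class = "zoo_entry"
    )
  })
  names(entries) <- paste(meta$species, meta$endpoint, sep = ".")
  if (anyDuplicated(names(entries)) || length(entries) != 18L) {
    stop("packaged zoo data is corrupted: expected 18 unique entries",
         call. = FALSE)
  }
  entries
}

#' Look up one zoo entry
#'
#' @param species,endpoint Species and endpoint identifiers (see
#'   [load_zoo()]).
#' @param zoo A zoo list from [load_zoo()]; loaded on demand by default.
#' @return A \code{zoo_entry}.
#' @export
zoo_entry <- function(species, endpoint, zoo = load_zoo()) {
  key <- paste(match.arg(species, species_levels),
               match.arg(endpoint, endpoint_levels), sep = ".")
  if (!key %in% names(zoo)) {
    stop("no zoo entry for ", key, call. = FALSE)
  }
  zoo[[key]]
}

#' @export
print.zoo_entry <- function(x, ...) {
  cat(sprintf("<zoo_entry %s %s  %s  %s/%s  %s  input scale: %s>\n",
              x$species, x$endpoint, x$architecture,
              x$params$hidden_activation, x$params$output_activation,
              x$trainer_name, x$input_scale))
  if (length(x$caveats)) {
    cat(paste0("  caveat: ", x$caveats, "\n"), sep = "")
  }
  invisible(x)
}

#' Validate a zoo entry against its recorded metadata
#'
#' Checks (a) that the parameter vectors agree with the stated architecture
#' string, (b) that all parameters are finite, (c) that the printed neuron
#' indices are complete (no skipped rows), and echoes the transcription
#' caveats. Reports; never repairs and never throws.
#'
#' @param entry A \code{zoo_entry}.
#' @return A list with \code{species}, \code{endpoint}, \code{checks} (a
#'   [tibble::tibble()] of check/pass/detail), \code{all_pass} and
#'   \code{caveats}.
#' @export
validate_entry <- function(entry) {
  stopifnot(inherits(entry, "zoo_entry"))
  H <- hidden_size(entry$params)
  stated_H <- as.integer(strsplit(entry$architecture, "-", fixed = TRUE)[[1]][2])
  idx <- entry$neuron_index
  checks <- tibble::tibble(
    check = c("architecture_agreement", "finite_parameters",
              "contiguous_neuron_rows"),
    pass = c(
      H == stated_H,
      all(is.finite(c(entry$params$input_weights, entry$params$hidden_biases,
                      entry$params$output_weights, entry$params$output_bias))),
      identical(idx, seq_len(length(idx)))
    ),
    detail = c(
      sprintf("architecture %s vs %d packaged rows", entry$architecture, H),
      "all weights and biases finite",
      if (identical(idx, seq_len(length(idx)))) "printed rows 1..H present"
      else sprintf("printed neuron indices: %s", paste(idx, collapse = ","))
    )
  )
  list(
    species = entry$species,
    endpoint = entry$endpoint,
    checks = checks,
    all_pass = all(checks$pass),
    caveats = entry$caveats
  )
}

#' Predict an endpoint from a published network
#'
#' Runs the forward pass of the transcribed network for one species/endpoint.
#' Because the printed weights' input scale is unresolved (see [load_zoo()]),
#' the result carries the entry's \code{input_scale} tag and caveats.
#' Concentrations outside the species' tested range are refused unless
#' extrapolation is explicitly allowed.
#'
#' @inheritParams zoo_entry
#' @param c Concentration(s), uL/L.
#' @param scale \code{"raw_uL_per_L"} (default) feeds \code{c} directly to the
#'   network; \code{"normalized01"} first maps the species' tested range to
#'   0-1.
#' @param allow_extrapolation Permit concentrations outside the tested range.
#' @return A list of class \code{zoo_prediction}: \code{value} (numeric,
#'   length of \code{c}), \code{species}, \code{endpoint}, \code{input_scale}
#'   (the entry's recorded tag), \code{scale_used}, \code{caveats}.
#' @export
zoo_predict <- function(species, endpoint, c,
                        scale = c("raw_uL_per_L", "normalized01"),
                        allow_extrapolation = FALSE,
                        zoo = load_zoo()) {
  scale <- match.arg(scale)
  entry <- zoo_entry(species, endpoint, zoo)
  c <- as.numeric(c)
  if (length(c) < 1L || anyNA(c) || any(!is.finite(c))) {
    stop("zoo_predict(): concentrations must be finite", call. = FALSE)
  }
  rng <- species_dose_range[[entry$species]]
  if (!allow_extrapolation && any(c < rng[1] | c > rng[2])) {
    stop("concentration outside the tested range [", rng[1], ", ", rng[2],
         "] uL/L for ", entry$species,
         "; set allow_extrapolation = TRUE to override", call. = FALSE)
  }
  x <- if (scale == "normalized01") (c - rng[1]) / (rng[2] - rng[1]) else c
  structure(
    list(
      value = predict_batch(entry$params, x),
      species = entry$species,
      endpoint = entry$endpoint,
      input_scale = entry$input_scale,
      scale_used = scale,
      caveats = entry$caveats
    ),
    class = "zoo_prediction"
  )
}

#' @export
print.zoo_prediction <- function(x, ...) {
  cat(sprintf("<zoo_prediction %s %s  input scale %s (%s)>\n",
              x$species, x$endpoint, x$scale_used, x$input_scale))
  print(x$value)
  invisible(x)
}

card_fields <- c("species", "endpoint", "architecture", "trainer_name",
                 "hidden_activation", "output_activation", "input_weights",
                 "hidden_biases", "output_weights", "output_bias",
                 "input_scale", "caveats")

#' Export / import a model card
#'
#' A model card is a JSON document carrying every field of a zoo entry at full
#' precision, so a network can be archived or exchanged and reloaded
#' losslessly.
#'
#' @param entry A \code{zoo_entry}.
#' @param path Optional file path; when given the JSON is also written there.
#' @return \code{export_model_card}: the JSON document (character scalar).
#'   \code{import_model_card}: the reconstructed \code{zoo_entry}.
#' @export
export_model_card <- function(entry, path = NULL) {
  stopifnot(inherits(entry, "zoo_entry"))
  doc <- jsonlite::toJSON(
    list(
      species = entry$species,
      endpoint = entry$endpoint,
      architecture = entry$architecture,
      trainer_name = entry$trainer_name,
      hidden_activation = entry$params$hidden_activation,
      output_activation = entry$params$output_activation,
      input_weights = entry$params$input_weights,
      hidden_biases = entry$params$hidden_biases,
      output_weights = entry$params$output_weights,
      output_bias = entry$params$output_bias,
      neuron_index = entry$neuron_index,
      input_scale = entry$input_scale,
      caveats = entry$caveats
    ),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  if (!is.null(path)) writeLines(doc, path)
  as.character(doc)
}

#' @rdname export_model_card
#' @param document JSON text (or a path to a JSON file) produced by
#'   [export_model_card()] or written by hand with the same schema.
#' @export
import_model_card <- function(document) {
  if (length(document) == 1L && !grepl("{", document, fixed = TRUE) &&
      file.exists(document)) {
    document <- paste(readLines(document), collapse = "\n")
  }
  x <- jsonlite::fromJSON(document, simplifyVector = TRUE)
  required <- setdiff(card_fields, "caveats")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("model card parse error: missing field(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  H <- length(x$input_weights)
  structure(
    list(
      species = x$species,
      endpoint = x$endpoint,
      architecture = x$architecture,
      trainer_name = x$trainer_name,
      params = ann_network(x$input_weights, x$hidden_biases,
                           x$output_weights, x$output_bias,
                           hidden_activation = x$hidden_activation,
                           output_activation = x$output_activation),
      neuron_index = if (!is.null(x$neuron_index)) as.integer(x$neuron_index)
                     else seq_len(H),
      input_scale = x$input_scale,
      caveats = if (is.null(x$caveats)) character(0) else as.character(x$caveats)
    ),
    class = "zoo_entry"
  )
}
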
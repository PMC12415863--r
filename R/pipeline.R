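#' Min-max normalization to the unit interval
#'
#' Scales values to \eqn{(v - \min)/(\max - \min) \in [0, 1]}. The returned
#' parameters let new data (e.g. a held-out test set) be scaled identically
#' and predictions be mapped back to native units.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return \code{minmax_normalize}: list with \code{scaled} and \code{params}
#'   (list \code{min}, \code{max}). \code{denormalize}: the native-unit
#'   vector.
#' @export
minmax_normalize <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values) || any(!is.finite(values))) {
    stop("minmax_normalize(): need >= 2 finite values", call. = FALSE)
  }
  lo <- min(values); hi <- max(values)
  if (hi == lo) {
    stop("degenerate range: all values equal", call. = FALSE)
  }
  list(scaled = (values - lo) / (hi - lo), params = list(min = lo, max = hi))
}

#' @rdname minmax_normalize
#' @param scaled Values on the 0-1 scale.
#' @param params Normalization parameters from [minmax_normalize()].
#' @export
denormalize <- function(scaled, params) {
  stopifnot(is.list(params), params$max > params$min)
  scaled * (params$max - params$min) + params$min
}

# apply existing params to new values
apply_normalization <- function(values, params) {
  (values - params$min) / (params$max - params$min)
}

#' Stratified 18/12 train/test split
#'
#' Splits a 30-fish dataset (10 per concentration) into 18 training and 12
#' testing records, stratified by concentration (6 train + 4 test per dose)
#' with a seeded shuffle inside each stratum. Stratification guarantees every
#' dose level is represented in training, which an unstratified split of so
#' small a dataset cannot.
#'
#' @param records A records table as produced by [generate_dataset()] or
#'   [read_records()]: exactly 30 rows, 10 per concentration.
#' @param seed Integer seed for the within-stratum shuffle.
#' @return List with \code{train} (18 rows) and \code{test} (12 rows) tibbles;
#'   disjoint, union = input.
#' @export
split_dataset <- function(records, seed = 1L) {
  check_records(records)
  counts <- table(records$concentration_uL_per_L)
  if (nrow(records) != 30L || length(counts) != 3L || any(counts != 10L)) {
    stop("split_dataset(): expected 30 records, 10 per each of 3 doses",
         call. = FALSE)
  }
  idx <- with_preserved_seed(seed, {
    unlist(lapply(sort(unique(records$concentration_uL_per_L)), function(d) {
      rows <- which(records$concentration_uL_per_L == d)
      sample(rows, 6L)
    }))
  })
  list(train = records[sort(idx), , drop = FALSE],
       test = records[setdiff(seq_len(nrow(records)), sort(idx)), , drop = FALSE])
}

#' Fit one endpoint model and report both phases
#'
#' Trains a 1-H-1 network on the training records (input and output min-max
#' normalized using training-split parameters only, preventing leakage into
#' the test phase), then evaluates training and testing predictions in native
#' endpoint units.
#'
#' @param train,test Record tables from [split_dataset()].
#' @param endpoint Endpoint identifier (\code{"IT"}, ..., \code{"HCT"}).
#' @param H Hidden-layer size.
#' @param hidden_activation Hidden transfer function.
#' @param config A [trainer_config()].
#' @param seed Seed for network initialization.
#' @return A list of class \code{endpoint_fit}: \code{rows} (two-row
#'   [tibble::tibble()], phases \code{training}/\code{testing} with RMSE,
#'   MAPE + band and both R-squared variants), \code{net}, \code{norm_x},
#'   \code{norm_y}, \code{train_result}, plus the fitted configuration
#'   metadata.
#' @export
fit_endpoint <- function(train, test, endpoint, H = 6L,
                         hidden_activation = "purelin",
                         config = trainer_config("rp"), seed = 1L) {
  check_records(train); check_records(test)
  endpoint <- match.arg(endpoint, endpoint_levels)
  col <- endpoint_column(endpoint)
  species <- unique(c(train$species, test$species))
  if (length(species) != 1L) {
    stop("fit_endpoint(): records mix species", call. = FALSE)
  }
  nx <- minmax_normalize(train$concentration_uL_per_L)
  ny <- minmax_normalize(train[[col]])
  net0 <- init_network(H, hidden_activation, seed = seed)
  fit <- switch(config$algorithm,
    gda = train_gda(net0, nx$scaled, ny$scaled, config),
    rp = train_rp(net0, nx$scaled, ny$scaled, config),
    seq = train_seq(net0, nx$scaled, ny$scaled, config)
  )
  phase_row <- function(phase, recs) {
    xs <- apply_normalization(recs$concentration_uL_per_L, nx$params)
    pred <- denormalize(predict_batch(fit$net, xs), ny$params)
    m <- eval_metrics(recs[[col]], pred)
    tibble::tibble(
      species = species, endpoint = endpoint,
      architecture = sprintf("1-%d-1", H),
      hidden_activation = hidden_activation,
      trainer = config$algorithm, phase = phase,
      rmse = m$rmse, mape = m$mape, mape_band = m$mape_band,
      r2_paper = m$r2_paper, r2_conventional = m$r2_conventional, n = m$n
    )
  }
  structure(
    list(
      rows = rbind(phase_row("training", train), phase_row("testing", test)),
      net = fit$net,
      norm_x = nx$params, norm_y = ny$params,
      train_result = fit,
      species = species, endpoint = endpoint, H = as.integer(H),
      hidden_activation = hidden_activation, trainer = config$algorithm
    ),
    class = "endpoint_fit"
  )
}

#' Predict an endpoint in native units from a fitted model
#'
#' @param fit An \code{endpoint_fit} from [fit_endpoint()] or
#'   [architecture_search()].
#' @param c Concentration(s), uL/L.
#' @return Numeric predictions in the endpoint's native units.
#' @export
predict_endpoint <- function(fit, c) {
  stopifnot(inherits(fit, "endpoint_fit"))
  denormalize(predict_batch(fit$net, apply_normalization(as.numeric(c), fit$norm_x)),
              fit$norm_y)
}

#' Default architecture-search grid
#'
#' Hidden sizes 4-10 (the range the published models span), the three
#' trainable hidden transfer functions, and the three training algorithms.
#'
#' @return A data.frame with one row per grid cell, in fixed grid order.
#' @export
default_search_grid <- function() {
  expand.grid(
    H = 4:10,
    hidden_activation = c("purelin", "tansig", "logsig_standard"),
    trainer = c("gda", "rp", "seq"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
}

#' Trial-and-error architecture search for one endpoint
#'
#' Trains every cell of the grid on the (normalized) training split and scores
#' each by held-out conventional R-squared, mirroring a systematic
#' trial-and-error model selection: the winner has the highest test R-squared;
#' ties are broken by the smaller |train - test| R-squared gap (least
#' overfitting), then by fewer hidden neurons, then by grid order. Selection
#' uses the conventional R-squared because the printed-form variant saturates
#' near 1 and cannot rank models.
#'
#' @inheritParams fit_endpoint
#' @param grid Data frame of cells (\code{H}, \code{hidden_activation},
#'   \code{trainer}), default [default_search_grid()].
#' @param seed Base seed; each cell's initialization seed is derived as
#'   \code{(seed * 127 + cell_index) mod (2^31 - 1)}.
#' @param trainer_defaults Optional named list overriding [trainer_config()]
#'   arguments shared by all cells (e.g. \code{max_epochs}).
#' @return A list of class \code{arch_search}: \code{best} (the winning
#'   \code{endpoint_fit}), \code{leaderboard} (one row per cell with train and
#'   test R-squared, gap, epochs and rank), \code{endpoint}, \code{seed}.
#' @export
architecture_search <- function(train, test, endpoint,
                                grid = default_search_grid(), seed = 1L,
                                trainer_defaults = list()) {
  if (!is.data.frame(grid) || nrow(grid) == 0L) {
    stop("architecture_search(): empty grid", call. = FALSE)
  }
  endpoint <- match.arg(endpoint, endpoint_levels)
  fits <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    cell <- grid[k, ]
    cfg <- do.call(trainer_config,
                   c(list(algorithm = cell$trainer), trainer_defaults))
    cell_seed <- (seed * 127 + k) %% 2147483647
    res <- tryCatch(
      fit_endpoint(train, test, endpoint, H = cell$H,
                   hidden_activation = cell$hidden_activation,
                   config = cfg, seed = cell_seed),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      rows[[k]] <- tibble::tibble(
        H = cell$H, hidden_activation = cell$hidden_activation,
        trainer = cell$trainer, train_r2 = NA_real_, test_r2 = NA_real_,
        r2_gap = NA_real_, test_mape = NA_real_, epochs = NA_integer_,
        error = conditionMessage(res)
      )
    } else {
      fits[[k]] <- res
      tr <- res$rows[res$rows$phase == "training", ]
      te <- res$rows[res$rows$phase == "testing", ]
      rows[[k]] <- tibble::tibble(
        H = cell$H, hidden_activation = cell$hidden_activation,
        trainer = cell$trainer, train_r2 = tr$r2_conventional,
        test_r2 = te$r2_conventional,
        r2_gap = abs(tr$r2_conventional - te$r2_conventional),
        test_mape = te$mape, epochs = res$train_result$epochs_run,
        error = NA_character_
      )
    }
  }
  leaderboard <- do.call(rbind, rows)
  ok <- which(!is.na(leaderboard$test_r2))
  if (length(ok) == 0L) {
    stop("architecture search failed: every grid cell diverged\n",
         paste(utils::head(leaderboard$error, 5), collapse = "\n"),
         call. = FALSE)
  }
  ord <- ok[order(-leaderboard$test_r2[ok], leaderboard$r2_gap[ok],
                  leaderboard$H[ok], ok)]
  leaderboard$rank <- NA_integer_
  leaderboard$rank[ord] <- seq_along(ord)
  structure(
    list(best = fits[[ord[1L]]], leaderboard = leaderboard,
         endpoint = endpoint, seed = as.integer(seed)),
    class = "arch_search"
  )
}

#' @export
print.arch_search <- function(x, ...) {
  b <- x$best
  cat(sprintf("<arch_search %s %s  best: 1-%d-1 %s/%s>\n",
              b$species, x$endpoint, b$H, b$hidden_activation, b$trainer))
  invisible(x)
}

#' Assemble a performance report
#'
#' Collects per-phase fit rows into the canonical species x endpoint x phase
#' performance table (RMSE, MAPE + accuracy band, both R-squared variants).
#'
#' @param rows A list of two-row tibbles from [fit_endpoint()] (the
#'   \code{rows} element, or \code{endpoint_fit}/\code{arch_search} objects
#'   directly), or a single combined data frame.
#' @return A [tibble::tibble()] with fixed column order, sorted by species,
#'   endpoint and phase.
#' @export
performance_report <- function(rows) {
  if (is.data.frame(rows)) rows <- list(rows)
  rows <- lapply(rows, function(r) {
    if (inherits(r, "arch_search")) r <- r$best
    if (inherits(r, "endpoint_fit")) r <- r$rows
    r
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) {
    stop("performance_report(): no rows", call. = FALSE)
  }
  cols <- c("species", "endpoint", "architecture", "hidden_activation",
            "trainer", "phase", "rmse", "mape", "mape_band", "r2_paper",
            "r2_conventional", "n")
  if (!all(cols %in% names(out))) {
    stop("performance_report(): malformed rows", call. = FALSE)
  }
  key <- paste(out$species, out$endpoint, out$phase)
  if (anyDuplicated(key)) {
    stop("duplicate (species, endpoint, phase) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  out <- out[order(match(out$species, species_levels),
                   match(out$endpoint, endpoint_levels),
                   match(out$phase, c("training", "testing"))), cols]
  tibble::as_tibble(out)
}

#' Render a performance report as aligned text
#'
#' @param report A table from [performance_report()].
#' @return Character vector of aligned lines (also printed invisibly usable
#'   with \code{cat}).
#' @export
format_performance_report <- function(report) {
  header <- sprintf("%-16s %-4s %-8s %-8s %10s %9s %-14s %9s %9s",
                    "species", "par", "arch", "phase", "RMSE", "MAPE(%)",
                    "band", "R2", "R2(print)")
  lines <- sprintf("%-16s %-4s %-8s %-8s %10.4f %9.3f %-14s %9.4f %9.4f",
                   report$species, report$endpoint, report$architecture,
                   report$phase, report$rmse, report$mape, report$mape_band,
                   report$r2_conventional, report$r2_paper)
  c(header, lines)
}

#' Welfare-limited dose recommendation
#'
#' Scans candidate concentrations and returns the lowest one whose predicted
#' induction time is at most \code{it_max} seconds and predicted recovery time
#' at most \code{rt_max} seconds (the acceptability thresholds for a usable
#' anesthetic dose: 180 s induction, 300 s recovery). If no dose satisfies
#' both, the induction-time-minimizing dose is reported with
#' \code{constraints_met = FALSE}.
#'
#' @param fit_it,fit_rt \code{endpoint_fit} models for IT and RT of the same
#'   species.
#' @param dose_range Numeric length-2 range of concentrations to scan, uL/L.
#' @param step Scan step, uL/L (default 1).
#' @param it_max,rt_max Constraint thresholds in seconds.
#' @return A list of class \code{dose_recommendation}: \code{species},
#'   \code{concentration}, \code{predicted_IT}, \code{predicted_RT},
#'   \code{constraints_met}.
#' @export
recommend_dose <- function(fit_it, fit_rt, dose_range, step = 1,
                           it_max = 180, rt_max = 300) {
  stopifnot(inherits(fit_it, "endpoint_fit"), inherits(fit_rt, "endpoint_fit"))
  if (fit_it$species != fit_rt$species) {
    stop("recommend_dose(): models are for different species", call. = FALSE)
  }
  if (length(dose_range) != 2L || !all(is.finite(dose_range)) ||
      dose_range[2] < dose_range[1]) {
    stop("recommend_dose(): invalid dose range", call. = FALSE)
  }
  doses <- seq(dose_range[1], dose_range[2], by = step)
  if (length(doses) == 0L) {
    stop("recommend_dose(): empty dose grid", call. = FALSE)
  }
  it <- predict_endpoint(fit_it, doses)
  rt <- predict_endpoint(fit_rt, doses)
  feasible <- which(it <= it_max & rt <= rt_max)
  pick <- if (length(feasible)) feasible[1L] else which.min(it)
  structure(
    list(
      species = fit_it$species,
      concentration = doses[pick],
      predicted_IT = it[pick],
      predicted_RT = rt[pick],
      constraints_met = length(feasible) > 0L,
      it_max = it_max, rt_max = rt_max
    ),
    class = "dose_recommendation"
  )
}

#' @export
print.dose_recommendation <- function(x, ...) {
  cat(sprintf(
    "<dose_recommendation %s  %g uL/L  IT %.1f s (<= %g: %s)  RT %.1f s (<= %g: %s)>\n",
    x$species, x$concentration,
    x$predicted_IT, x$it_max, x$predicted_IT <= x$it_max,
    x$predicted_RT, x$rt_max, x$predicted_RT <= x$rt_max))
  invisible(x)
}
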
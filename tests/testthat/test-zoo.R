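test_that("the zoo loads all 18 published networks with their metadata", {
  zoo <- load_zoo()
  expect_length(zoo, 18L)
  combos <- expand.grid(
    species = c("common_carp", "danube_sturgeon", "rainbow_trout"),
    endpoint = c("IT", "RT", "WBC", "RBC", "HGB", "HCT"))
  expect_setequal(names(zoo), paste(combos$species, combos$endpoint, sep = "."))

  carp_wbc <- zoo_entry("common_carp", "WBC", zoo)
  expect_identical(carp_wbc$architecture, "1-6-1")
  expect_identical(carp_wbc$params$hidden_activation, "purelin")
  expect_identical(carp_wbc$trainer_name, "trainrp")

  sturgeon_it <- zoo_entry("danube_sturgeon", "IT", zoo)
  expect_identical(sturgeon_it$params$hidden_biases[1], 124.454)
  expect_identical(sturgeon_it$architecture, "1-10-1")
  expect_identical(sturgeon_it$params$hidden_activation, "logsig_paper")

  trout_it <- zoo_entry("rainbow_trout", "IT", zoo)
  expect_identical(trout_it$params$hidden_activation, "tansig")
  expect_identical(trout_it$trainer_name, "trains")
  expect_identical(hidden_size(trout_it$params), 7L)  # printed rows only

  # every entry: unverified input scale, purelin output
  expect_true(all(vapply(zoo, function(e) e$input_scale, "") == "unverified"))
  expect_true(all(vapply(zoo, function(e) e$params$output_activation, "") ==
                    "purelin"))

  # logsig dialect switch
  zoo_std <- load_zoo(logsig_dialect = "standard")
  expect_identical(zoo_entry("danube_sturgeon", "IT", zoo_std)$params$hidden_activation,
                   "logsig_standard")
})

test_that("packaged transcription string-matches the frozen table copy", {
  pkg_w <- read.csv(system.file("extdata", "zoo_weights.csv",
                                package = "anesdose"),
                    colClasses = "character")
  frozen_w <- read.csv(test_path("zoo-transcription-frozen-weights.csv"),
                       colClasses = "character")
  expect_identical(pkg_w, frozen_w)

  pkg_m <- read.csv(system.file("extdata", "zoo_meta.csv",
                                package = "anesdose"),
                    colClasses = "character")
  frozen_m <- read.csv(test_path("zoo-transcription-frozen-meta.csv"),
                       colClasses = "character")
  expect_identical(pkg_m, frozen_m)

  # loaded numeric parameters equal the printed strings exactly (no silent
  # sign or row repairs)
  zoo <- load_zoo()
  for (key in names(zoo)) {
    e <- zoo[[key]]
    block <- frozen_w[frozen_w$species == e$species &
                        frozen_w$endpoint == e$endpoint, ]
    expect_identical(e$params$input_weights, as.numeric(block$w1), label = key)
    expect_identical(e$params$hidden_biases, as.numeric(block$theta_i),
                     label = key)
    expect_identical(e$params$output_weights, as.numeric(block$lw), label = key)
    expect_identical(e$neuron_index, as.integer(block$i), label = key)
    bias <- frozen_m$output_bias[frozen_m$species == e$species &
                                   frozen_m$endpoint == e$endpoint]
    expect_identical(e$params$output_bias, as.numeric(bias), label = key)
  }
})

test_that("validation reports printed inconsistencies without repairing them", {
  zoo <- load_zoo()
  ok <- validate_entry(zoo_entry("common_carp", "WBC", zoo))
  expect_true(ok$all_pass)
  expect_length(ok$caveats, 0)

  hct <- validate_entry(zoo_entry("common_carp", "HCT", zoo))
  expect_false(hct$checks$pass[hct$checks$check == "architecture_agreement"])
  expect_match(paste(hct$caveats, collapse = " "), "1-7-1.*8 rows")

  trout_it <- validate_entry(zoo_entry("rainbow_trout", "IT", zoo))
  expect_false(trout_it$checks$pass[trout_it$checks$check ==
                                      "contiguous_neuron_rows"])
  expect_match(paste(trout_it$caveats, collapse = " "), "i=3 absent")

  # every entry either passes all checks or carries a caveat explaining why
  for (e in zoo) {
    v <- validate_entry(e)
    expect_true(v$all_pass || length(v$caveats) > 0,
                label = paste(e$species, e$endpoint))
  }
})

test_that("zoo_predict agrees with the per-neuron oracle on all entries", {
  zoo <- load_zoo()
  ranges <- list(common_carp = c(800, 1400), danube_sturgeon = c(500, 1000),
                 rainbow_trout = c(400, 800))
  set.seed(77)
  for (e in zoo) {
    rng <- ranges[[e$species]]
    cs <- runif(100, rng[1], rng[2])
    pred <- zoo_predict(e$species, e$endpoint, cs, zoo = zoo)
    expect_identical(pred$input_scale, "unverified")
    oracle <- vapply(cs, oracle_forward, numeric(1), net = e$params)
    expect_equal(pred$value, oracle, tolerance = 1e-9)
    # and zoo_predict is exactly the packaged forward pass
    expect_equal(pred$value, predict_batch(e$params, cs), tolerance = 1e-12)
  }

  # frozen independent-oracle spot values
  expect_equal(zoo_predict("common_carp", "WBC", 800)$value, 40.02880255,
               tolerance = 1e-9)
  expect_equal(zoo_predict("danube_sturgeon", "IT", 750)$value, 373.737,
               tolerance = 1e-9)

  # trout RT at the three tested doses: finite values
  rt <- zoo_predict("rainbow_trout", "RT", c(400, 600, 800))
  expect_length(rt$value, 3)
  expect_true(all(is.finite(rt$value)))
})

test_that("predictions outside the tested range need an explicit override", {
  expect_error(zoo_predict("common_carp", "IT", 5000), "outside the tested range")
  expect_silent(zoo_predict("common_carp", "IT", 5000,
                            allow_extrapolation = TRUE))
  # normalized01 maps the tested range onto [0, 1] before the forward pass
  zoo <- load_zoo()
  e <- zoo_entry("common_carp", "IT", zoo)
  p <- zoo_predict("common_carp", "IT", 1100, scale = "normalized01", zoo = zoo)
  expect_equal(p$value, forward(e$params, 0.5), tolerance = 1e-12)
})

test_that("model cards round-trip losslessly and fail loudly on bad schema", {
  zoo <- load_zoo()
  for (key in c("common_carp.WBC", "rainbow_trout.IT", "danube_sturgeon.HCT")) {
    e <- zoo[[key]]
    back <- import_model_card(export_model_card(e))
    expect_identical(back$params$input_weights, e$params$input_weights)
    expect_identical(back$params$output_bias, e$params$output_bias)
    expect_identical(back$architecture, e$architecture)
    expect_identical(back$caveats, e$caveats)
    expect_identical(back$input_scale, e$input_scale)
  }

  # file round trip
  path <- withr::local_tempfile(fileext = ".json")
  export_model_card(zoo[["common_carp.WBC"]], path)
  expect_identical(import_model_card(path)$params$hidden_biases,
                   zoo[["common_carp.WBC"]]$params$hidden_biases)

  doc <- jsonlite::fromJSON(export_model_card(zoo[["common_carp.WBC"]]))
  doc$output_bias <- NULL
  expect_error(import_model_card(jsonlite::toJSON(doc, auto_unbox = TRUE)),
               "output_bias")

  # hand-written minimal card is usable
  minimal <- jsonlite::toJSON(list(
    species = "common_carp", endpoint = "IT", architecture = "1-1-1",
    trainer_name = "traingda", hidden_activation = "purelin",
    output_activation = "purelin", input_weights = 1, hidden_biases = 0,
    output_weights = 1, output_bias = 0, input_scale = "raw_uL_per_L"),
    auto_unbox = TRUE, digits = NA)
  e_min <- import_model_card(minimal)
  expect_equal(forward(e_min$params, 900), 900)
})
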
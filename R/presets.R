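#' Population presets for the synthetic flower-colour data generator
#'
#' A preset bundles everything the generator needs to emulate one of the two
#' study populations of *Silene littorea* on the Galician coast: trait means
#' and SDs, the standardized coefficients of the causal structure linking
#' corolla colour, calyx colour, flower number, ovary predation and seed
#' production, the display-flower correlation, and the pollen-production and
#' pollen-dispersal parameters used for male fitness.
#'
#' Two named presets are provided. `"barra-like"` emulates a population in
#' which corolla colour increases both calyx colour (0.36) and flower number
#' (0.30), flower number drives ovary predation (0.58) and seed production
#' (1.03), and ovary predation depresses seed production (-0.45).
#' `"melide-like"` has a negative corolla-to-flower-number path (-0.37),
#' strong flower-to-predation (0.76) and flower-to-seeds (0.82) paths, and no
#' corolla-to-calyx or predation-to-seeds effect.
#'
#' Count-valued traits are produced by rounding a latent Gaussian variable
#' and clamping at zero, and corolla colour is truncated below at an R:G
#' ratio of 1 (a ratio below 1 would mean greener-than-red petals). Both
#' operations distort raw moments and attenuate regression coefficients, so
#' each named preset carries latent-scale parameters calibrated such that the
#' *observed* (rounded, clamped) variables reproduce the quoted means, SDs,
#' correlations and standardized coefficients. See [calibrate_preset()] to
#' re-derive them.
#'
#' @param name preset name, one of `"barra-like"`, `"melide-like"`.
#' @return An object of class `"population_preset"`: a list with elements
#'   `name`, `n_default`, `trait_moments` (named list of `c(mean, sd)`),
#'   `path_coefficients` (named standardized coefficients of the generating
#'   DAG), `display_flower_corr`, `pollen_production` (`mean`, `se`, `n`),
#'   `dispersal_fraction_moments`, `noise_sds`, and the internal `latent`
#'   parameter block.
#' @seealso [simulate_population()], [calibrate_preset()]
#' @examples
#' pr <- population_preset("barra-like")
#' pr$trait_moments$flowers_total
#' @export
population_preset <- function(name) {
  valid <- c("barra-like", "melide-like")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid))
    stop("unknown preset; valid presets are: ",
         paste(sQuote(valid), collapse = ", "), call. = FALSE)

  if (name == "barra-like") {
    trait_moments <- list(
      corolla_color            = c(mean = 1.29,   sd = 0.18),
      calyx_color              = c(mean = 1.35,   sd = 0.10),
      corolla_area             = c(mean = 2.46,   sd = 0.50),
      calyx_length             = c(mean = 1.71,   sd = 0.26),
      ovules_per_flower        = c(mean = 66.85,  sd = 10.00),
      floral_display           = c(mean = 2.51,   sd = 1.52),
      flowers_total            = c(mean = 17.41,  sd = 11.40),
      ovaries_predated         = c(mean = 2.71,   sd = 3.21),
      percent_corolla_predated = c(mean = 0.49,   sd = 1.04),
      fruit_set                = c(mean = 0.32,   sd = 0.16),
      seeds_per_fruit          = c(mean = 43.04,  sd = 14.00),
      seeds_per_plant          = c(mean = 272.69, sd = 251.55))
    path_coefficients <- c(
      "corolla_color->calyx_color"        = 0.36,
      "corolla_color->flowers_total"      = 0.30,
      "flowers_total->ovaries_predated"   = 0.58,
      "ovaries_predated->seeds_per_plant" = -0.45,
      "flowers_total->seeds_per_plant"    = 1.03)
    display_flower_corr <- 0.49
    pollen_production <- c(mean = 21711.33, se = 620.28, n = 30)
    dispersed_per_flower <- c(mean = 17856.10, sd = 5076.38)
  } else {
    trait_moments <- list(
      corolla_color            = c(mean = 1.25,   sd = 0.17),
      calyx_color              = c(mean = 1.43,   sd = 0.10),
      corolla_area             = c(mean = 1.85,   sd = 0.41),
      calyx_length             = c(mean = 1.78,   sd = 0.16),
      ovules_per_flower        = c(mean = 62.20,  sd = 8.07),
      floral_display           = c(mean = 3.02,   sd = 2.22),
      flowers_total            = c(mean = 17.12,  sd = 12.44),
      ovaries_predated         = c(mean = 3.66,   sd = 4.70),
      percent_corolla_predated = c(mean = 1.00,   sd = 1.56),
      fruit_set                = c(mean = 0.24,   sd = 0.15),
      seeds_per_fruit          = c(mean = 30.79,  sd = 14.99),
      seeds_per_plant          = c(mean = 126.37, sd = 139.11))
    path_coefficients <- c(
      "corolla_color->calyx_color"        = 0,
      "corolla_color->flowers_total"      = -0.37,
      "flowers_total->ovaries_predated"   = 0.76,
      "ovaries_predated->seeds_per_plant" = 0,
      "flowers_total->seeds_per_plant"    = 0.82)
    display_flower_corr <- 0.83
    pollen_production <- c(mean = 18192.3, se = 561.4, n = 42)
    dispersed_per_flower <- c(mean = 16222.72, sd = 3206.86)
  }

  # Dispersal fraction: dispersed-per-flower moments divided by the
  # population mean pollen production; drawn from a moment-matched Beta so
  # the fraction lives in [0, 1] without clamping bias.
  dfm <- c(mean = unname(dispersed_per_flower["mean"] / pollen_production["mean"]),
           sd = unname(dispersed_per_flower["sd"] / pollen_production["mean"]))

  preset <- structure(list(
    name = name,
    n_default = 50L,
    trait_moments = trait_moments,
    path_coefficients = path_coefficients,
    display_flower_corr = display_flower_corr,
    pollen_production = pollen_production,
    dispersal_fraction_moments = dfm,
    assay = c(suspension_volume_ul = 1500, subsample_volume_ul = 10,
              n_subsamples = 10, anthers_per_flower = 10),
    gynomonoecious_prob = 0.15,
    latent = NULL), class = "population_preset")

  cal <- .preset_calibration[[name]]
  preset$latent <- if (!is.null(cal)) cal else latent_init(preset)
  preset$noise_sds <- preset$latent$resid_sd
  validate_preset(preset)
  preset
}

# Variables of the generating DAG, in topological order.
sem_variables <- function() c("corolla_color", "calyx_color", "flowers_total",
                              "ovaries_predated", "seeds_per_plant")

validate_preset <- function(preset) {
  sds <- vapply(preset$trait_moments, function(m) m[["sd"]], 0)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("preset trait SDs must be finite and >= 0", call. = FALSE)
  dfm <- preset$dispersal_fraction_moments
  if (dfm["mean"] < 0 || dfm["mean"] > 1)
    stop("dispersal fraction mean must lie in [0, 1]", call. = FALSE)
  if (any(!is.finite(unlist(preset$path_coefficients))))
    stop("non-finite path coefficient in preset", call. = FALSE)
  invisible(preset)
}

# Analytic first guess for the latent parameter block: unstandardized
# coefficients from the quoted standardized ones and Table-scale SDs, latent
# moments moment-matched through the censoring/truncation maps.
latent_init <- function(preset) {
  tm <- preset$trait_moments
  pc <- preset$path_coefficients
  sd_of <- function(v) tm[[v]][["sd"]]
  mean_of <- function(v) tm[[v]][["mean"]]

  b <- c(
    cc = pc[["corolla_color->calyx_color"]] * sd_of("calyx_color") / sd_of("corolla_color"),
    cf = pc[["corolla_color->flowers_total"]] * sd_of("flowers_total") / sd_of("corolla_color"),
    fo = pc[["flowers_total->ovaries_predated"]] * sd_of("ovaries_predated") / sd_of("flowers_total"),
    os = pc[["ovaries_predated->seeds_per_plant"]] * sd_of("seeds_per_plant") / sd_of("ovaries_predated"),
    fs = pc[["flowers_total->seeds_per_plant"]] * sd_of("seeds_per_plant") / sd_of("flowers_total"))

  expl <- function(x) sqrt(max(0.05, 1 - x^2))
  mu <- c(corolla_color = mean_of("corolla_color"),
          calyx_color = mean_of("calyx_color"),
          flowers_total = mean_of("flowers_total"),
          ovaries_predated = mean_of("ovaries_predated"),
          seeds_per_plant = mean_of("seeds_per_plant"),
          floral_display = mean_of("floral_display"))
  resid_sd <- c(
    corolla_color = sd_of("corolla_color"),
    calyx_color = sd_of("calyx_color") * expl(pc[["corolla_color->calyx_color"]]),
    flowers_total = sd_of("flowers_total") * expl(pc[["corolla_color->flowers_total"]]),
    ovaries_predated = sd_of("ovaries_predated") * expl(pc[["flowers_total->ovaries_predated"]]),
    seeds_per_plant = sd_of("seeds_per_plant") * sqrt(0.3),
    floral_display = sd_of("floral_display"))

  list(mu = mu, resid_sd = resid_sd, coef = b,
       display_latent_corr = preset$display_flower_corr)
}

#' @export
print.population_preset <- function(x, ...) {
  cat("Population preset:", x$name, "\n")
  cat("  traits:", paste(names(x$trait_moments), collapse = ", "), "\n")
  pc <- x$path_coefficients
  cat("  generating paths (standardized):\n")
  for (e in names(pc)) cat(sprintf("    %-36s %6.2f\n", e, pc[[e]]))
  cat(sprintf("  display-flower correlation: %.2f\n", x$display_flower_corr))
  cat(sprintf("  pollen production/flower: %.2f (SE %.2f, n = %d)\n",
              x$pollen_production[["mean"]], x$pollen_production[["se"]],
              as.integer(x$pollen_production[["n"]])))
  invisible(x)
}

#' Serialize a population preset to JSON
#'
#' @param preset a [population_preset()] object.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when writing to a file).
#' @export
preset_to_json <- function(preset, path = NULL) {
  stopifnot(inherits(preset, "population_preset"))
  # named atomic vectors become JSON objects, not nameless arrays
  jsonable <- function(x) {
    if (is.list(x)) lapply(x, jsonable)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  js <- jsonlite::toJSON(jsonable(unclass(preset)), auto_unbox = TRUE,
                         digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a population preset back from JSON
#'
#' @param path file path or JSON string produced by [preset_to_json()].
#' @return A `population_preset` object.
#' @export
preset_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  for (f in c("trait_moments", "latent"))
    obj[[f]] <- lapply(obj[[f]], function(x) unlist(x))
  for (f in c("path_coefficients", "display_flower_corr", "pollen_production",
              "dispersal_fraction_moments", "assay", "noise_sds"))
    obj[[f]] <- unlist(obj[[f]])
  obj$latent$display_latent_corr <- unname(obj$latent$display_latent_corr)
  structure(obj, class = "population_preset")
}
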
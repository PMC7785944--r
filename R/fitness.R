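#' Female fitness components per plant
#'
#' Derives, from raw flower/fruit/seed counts, the per-plant female fitness
#' components: fruit-set (fruits over total flowers), per-fruit ovule counts
#' (ripe + aborted), seed-set (ripe over ovules, averaged over the up-to-3
#' sampled fruits), mean seeds per fruit, and total female fitness as seeds
#' per plant = mean seeds per fruit x total fruit production. Both female
#' and hermaphrodite flowers count towards female fitness.
#'
#' Sampled fruits with zero ovules (ripe + aborted = 0) are excluded from
#' the per-fruit means; a message reports how many were dropped. Missing
#' inputs propagate as `NA` outputs.
#'
#' @param plants a plant table (see [simulate_population()] /
#'   [read_plant_table()]) with columns `flowers_total`, `fruits_total` and
#'   `fruit1_ripe` ... `fruit3_aborted`.
#' @return A `data.frame` with columns `plant_id`, `fruit_set`, `seed_set`,
#'   `ovules_per_flower`, `seeds_per_fruit`, `seeds_per_plant`.
#' @export
female_fitness_components <- function(plants) {
  stopifnot(is.data.frame(plants))
  n <- nrow(plants)
  ripe <- as.matrix(plants[, paste0("fruit", 1:3, "_ripe"), drop = FALSE])
  abrt <- as.matrix(plants[, paste0("fruit", 1:3, "_aborted"), drop = FALSE])
  ovules <- ripe + abrt

  empty <- !is.na(ovules) & ovules == 0
  if (any(empty)) {
    message(sum(empty), " sampled fruit(s) with zero ovules excluded from per-fruit means")
    ripe[empty] <- NA
    ovules[empty] <- NA
  }

  fl <- plants$flowers_total
  fr <- plants$fruits_total
  fruit_set <- ifelse(!is.na(fl) & fl >= 1, fr / fl, NA_real_)
  seeds_per_fruit <- rowMeans(ripe, na.rm = TRUE)
  seeds_per_fruit[!is.finite(seeds_per_fruit)] <- NA
  seed_set <- rowMeans(ripe / ovules, na.rm = TRUE)
  seed_set[!is.finite(seed_set)] <- NA
  ovules_pf <- rowMeans(ovules, na.rm = TRUE)
  ovules_pf[!is.finite(ovules_pf)] <- NA

  seeds_per_plant <- seeds_per_fruit * fr
  # a plant without fruits produced no seeds, regardless of sampled fruits
  seeds_per_plant[!is.na(fr) & fr == 0] <- 0
  fruitless <- !is.na(fr) & fr == 0
  seeds_per_fruit[fruitless & is.na(seeds_per_fruit)] <- NA

  data.frame(plant_id = plants$plant_id %||% seq_len(n),
             fruit_set = fruit_set, seed_set = seed_set,
             ovules_per_flower = ovules_pf,
             seeds_per_fruit = seeds_per_fruit,
             seeds_per_plant = seeds_per_plant,
             stringsAsFactors = FALSE)
}

#' Male fitness components per plant
#'
#' Scales the pollen-assay subsample counts up to undispersed grains per
#' flower, subtracts them from the population mean pollen production to get
#' dispersed grains per flower, and multiplies by the number of hermaphrodite
#' flowers for total male fitness. The counted grains refer to one or two
#' anthers washed in the suspension; the species bears ten stamens, so the
#' per-anther count is scaled by `anthers_per_flower` (default 10, exposed
#' because the anther-to-flower scaling is an assumption).
#'
#' Sampling noise can push the undispersed estimate above the population
#' mean production; negative dispersed counts are clamped to zero and
#' flagged in the `dispersal_clamped` column.
#'
#' @param plants plant table with `plant_id` and `flowers_hermaphrodite`.
#' @param assay assay table (see [simulate_pollen_assay()]): per plant,
#'   `anthers_counted` (1 or 2), `suspension_volume_ul`,
#'   `subsample_volume_ul` and subsample count columns `subsample_*`.
#' @param pop_mean_production mean pollen grains produced per flower in the
#'   population (> 0).
#' @param anthers_per_flower anthers borne by one flower; default 10.
#' @return A `data.frame` with columns `plant_id`, `undispersed_per_flower`,
#'   `dispersed_per_flower`, `dispersed_per_plant`, `dispersal_clamped`.
#' @export
male_fitness_components <- function(plants, assay, pop_mean_production,
                                    anthers_per_flower = 10) {
  stopifnot(is.data.frame(plants), is.data.frame(assay))
  stop_if_not_number(pop_mean_production, "pop_mean_production", 0, strict = TRUE)
  if (any(assay$suspension_volume_ul <= 0) || any(assay$subsample_volume_ul <= 0))
    stop("assay volumes must be positive", call. = FALSE)
  if (!all(assay$anthers_counted %in% c(1, 2)))
    stop("'anthers_counted' must be 1 or 2", call. = FALSE)

  sub_cols <- grep("^subsample_[0-9]+$", names(assay), value = TRUE)
  if (length(sub_cols) == 0) stop("no subsample count columns found", call. = FALSE)
  mean_count <- rowMeans(as.matrix(assay[, sub_cols, drop = FALSE]))

  undispersed_sample <- mean_count *
    assay$suspension_volume_ul / assay$subsample_volume_ul
  undispersed_per_flower <- undispersed_sample / assay$anthers_counted *
    anthers_per_flower
  dispersed_per_flower <- pop_mean_production - undispersed_per_flower
  clamped <- !is.na(dispersed_per_flower) & dispersed_per_flower < 0
  dispersed_per_flower[clamped] <- 0

  herm <- plants$flowers_hermaphrodite[match(assay$plant_id, plants$plant_id)]
  data.frame(plant_id = assay$plant_id,
             undispersed_per_flower = undispersed_per_flower,
             dispersed_per_flower = dispersed_per_flower,
             dispersed_per_plant = dispersed_per_flower * herm,
             dispersal_clamped = clamped,
             stringsAsFactors = FALSE)
}

#' Ovary predation per plant
#'
#' Proportion of predated ovaries relative to total ovaries; each flower
#' bears one ovary, so the denominator is the total flower count.
#'
#' @param plants plant table with `ovaries_predated` and `flowers_total`.
#' @return A `data.frame` with columns `plant_id` and
#'   `proportion_ovaries_predated` (in `[0, 1]`).
#' @export
herbivory_components <- function(plants) {
  stopifnot(is.data.frame(plants))
  bad <- !is.na(plants$ovaries_predated) & !is.na(plants$flowers_total) &
    plants$ovaries_predated > plants$flowers_total
  if (any(bad))
    stop("ovaries_predated exceeds flowers_total for plant(s): ",
         paste(utils::head(plants$plant_id[bad], 5), collapse = ", "),
         call. = FALSE)
  prop <- ifelse(!is.na(plants$flowers_total) & plants$flowers_total >= 1,
                 plants$ovaries_predated / plants$flowers_total, NA_real_)
  data.frame(plant_id = plants$plant_id %||% seq_len(nrow(plants)),
             proportion_ovaries_predated = prop, stringsAsFactors = FALSE)
}

#' All fitness and herbivory components of a plant table
#'
#' Convenience wrapper combining [female_fitness_components()],
#' [herbivory_components()] and, when an assay table is supplied,
#' [male_fitness_components()], into one per-plant table.
#'
#' @inheritParams female_fitness_components
#' @inheritParams male_fitness_components
#' @param assay optional pollen assay table; male components are `NA`
#'   without it (plants lacking assay data are excluded from male-fitness
#'   analyses downstream).
#' @return A per-plant `data.frame` of all components.
#' @export
fitness_components <- function(plants, assay = NULL,
                               pop_mean_production = NULL,
                               anthers_per_flower = 10) {
  out <- merge(female_fitness_components(plants), herbivory_components(plants),
               by = "plant_id", sort = FALSE)
  if (!is.null(assay)) {
    if (is.null(pop_mean_production))
      stop("'pop_mean_production' is required with an assay table", call. = FALSE)
    male <- male_fitness_components(plants, assay, pop_mean_production,
                                    anthers_per_flower)
    out <- merge(out, male, by = "plant_id", all.x = TRUE, sort = FALSE)
  }
  out[match(plants$plant_id, out$plant_id), , drop = FALSE]
}
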
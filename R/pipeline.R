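#' Read / write a plant-level CSV table
#'
#' The pipeline CSV schema has one row per plant with columns:
#' `plant_id`, `population`, the floral traits (`corolla_color`,
#' `calyx_color`, `corolla_area`, `calyx_length`, `ovules_per_flower`,
#' `floral_display`, `flowers_total`, `flowers_hermaphrodite`), fruit and
#' per-fruit seed counts (`fruits_total`, `fruit1_ripe` ...
#' `fruit3_aborted`), herbivory (`percent_corolla_predated`,
#' `ovaries_predated`) and optionally `seeds_per_plant`. Missing values are
#' empty cells.
#'
#' @param path CSV file path.
#' @return A `data.frame`.
#' @export
read_plant_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("plant_id", "population", "flowers_total")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("plant table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab$plant_id))
    stop("duplicated plant ids", call. = FALSE)
  tab
}

#' @rdname read_plant_table
#' @param tab plant table to write.
#' @export
write_plant_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Analysis configuration
#'
#' Collects every knob of the end-to-end pipeline in one validated list.
#'
#' @param input path to a plant CSV, or `NULL` to simulate from `preset`.
#' @param preset preset name for simulation (see [population_preset()]).
#' @param n number of plants to simulate per population.
#' @param seed master RNG seed for the run.
#' @param traits trait columns used in the selection analyses.
#' @param components absolute-fitness columns analysed; defaults to the
#'   female components plus total female fitness.
#' @param parametric trait/estimate names compared between populations with
#'   Welch's t-test; everything else uses the Wilcoxon rank-sum test.
#' @param sem_variables variable set for the path analysis.
#' @param sem_exogenous exogenous variable(s) of the path analysis.
#' @param df_set degrees of freedom of the enumerated near-saturated
#'   candidate models.
#' @param bootstrap_B bootstrap replicates for the selected model (>= 100).
#' @param alpha significance level used in trimming.
#' @param rescale_fitness divide total female fitness by 1,000 before path
#'   fitting, reducing the impact of its much larger variance.
#' @param out_dir optional output directory for TSV/JSON artifacts.
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(input = NULL, preset = NULL, n = 50, seed = 1,
                            traits = c("corolla_color", "calyx_color",
                                       "corolla_area", "calyx_length",
                                       "ovules_per_flower", "floral_display",
                                       "flowers_total"),
                            components = c("fruit_set", "fruits_total",
                                           "seed_set", "seeds_per_fruit",
                                           "seeds_per_plant"),
                            parametric = c("calyx_color", "ovules_per_flower",
                                           "seed_set", "seeds_per_fruit"),
                            sem_variables = c("corolla_color", "calyx_color",
                                              "flowers_total",
                                              "ovaries_predated",
                                              "seeds_per_plant"),
                            sem_exogenous = "corolla_color",
                            df_set = 1:2, bootstrap_B = 1000, alpha = 0.05,
                            rescale_fitness = TRUE, out_dir = NULL) {
  if (is.null(input) && is.null(preset))
    stop("supply 'input' or 'preset'", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (bootstrap_B < 100) stop("bootstrap_B must be >= 100", call. = FALSE)
  structure(list(input = input, preset = preset, n = n, seed = seed,
                 traits = traits, components = components,
                 parametric = parametric, sem_variables = sem_variables,
                 sem_exogenous = sem_exogenous, df_set = df_set,
                 bootstrap_B = bootstrap_B, alpha = alpha,
                 rescale_fitness = rescale_fitness, out_dir = out_dir),
            class = "analysis_config")
}

#' Population summary table
#'
#' Per trait/estimate and population: mean, SD, min, max, n and CV%; plus,
#' with exactly two populations, the between-population comparison --
#' Welch's t for the columns configured as parametric, the Wilcoxon
#' rank-sum test otherwise -- and Shapiro-Wilk normality screening p-values
#' (reported, not used to switch tests automatically).
#'
#' @param tab plant table (traits and derived estimates as columns).
#' @param columns columns to summarize.
#' @param parametric columns compared with Welch's t-test.
#' @param population name of the population column.
#' @return A `data.frame`, one row per column x population.
#' @export
summarize_populations <- function(tab, columns,
                                  parametric = character(0),
                                  population = "population") {
  stopifnot(is.data.frame(tab))
  missing_cols <- setdiff(columns, names(tab))
  if (length(missing_cols))
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  pops <- unique(tab[[population]])
  rows <- list()
  for (col in columns) {
    test_stat <- test_p <- NA_real_
    test_name <- NA_character_
    if (length(pops) == 2) {
      x <- tab[[col]][tab[[population]] == pops[1]]
      y <- tab[[col]][tab[[population]] == pops[2]]
      if (col %in% parametric) {
        tt <- welch_t(x[!is.na(x)], y[!is.na(y)])
        test_stat <- tt$t; test_p <- tt$p; test_name <- "welch_t"
      } else {
        wt <- wilcoxon_rank_sum(x, y)
        test_stat <- wt$W; test_p <- wt$p; test_name <- "wilcoxon"
      }
    }
    for (pop in pops) {
      v <- tab[[col]][tab[[population]] == pop]
      v <- v[!is.na(v)]
      sw <- if (length(v) >= 3 && length(unique(v)) > 1 && length(v) <= 5000)
        stats::shapiro.test(v)$p.value else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        variable = col, population = pop, mean = mean(v), sd = stats::sd(v),
        min = min(v), max = max(v), n = length(v),
        cv_percent = if (mean(v) != 0) cv_percent(mean(v), stats::sd(v))
                     else NA_real_,
        shapiro_p = sw, test = test_name, test_stat = test_stat,
        test_p = test_p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Executes, deterministically for a given config and seed: data ingestion
#' or simulation, fitness derivation, population summaries, selection
#' analysis (opportunities, differentials, gradients) per population and
#' fitness component, the Brown-Forsythe comparison of selection
#' opportunities across populations, and the path analysis (near-saturated
#' enumeration, AIC/BIC ranking, trimming, bootstrap inference, indirect
#' effect of corolla colour on female fitness). Every reported number comes
#' from one of the package's module functions.
#'
#' @param config an [analysis_config()].
#' @return A `report_bundle` list; written to `config$out_dir` when set.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))

  # ---- ingestion ----
  if (!is.null(config$input)) {
    tab <- read_plant_table(config$input)
  } else {
    presets <- lapply(config$preset, population_preset)
    tabs <- lapply(seq_along(presets), function(i)
      simulate_population(presets[[i]], n = config$n,
                          seed = config$seed + i - 1))
    tab <- do.call(rbind, tabs)
  }
  if (nrow(tab) == 0)
    stop("ingestion: empty plant table", call. = FALSE)

  # ---- fitness derivation ----
  fc <- fitness_components(tab)
  derived <- setdiff(names(fc), names(tab))
  tab <- cbind(tab, fc[derived])
  if (!"seeds_per_plant" %in% names(tab))
    tab$seeds_per_plant <- fc$seeds_per_plant

  # ---- population summaries ----
  summary_cols <- unique(c(config$traits, "percent_corolla_predated",
                           "ovaries_predated", config$components))
  summary_cols <- intersect(summary_cols, names(tab))
  summaries <- summarize_populations(tab, summary_cols,
                                     parametric = config$parametric)

  # ---- selection analysis ----
  components <- intersect(config$components, names(tab))
  selection <- selection_analysis(tab, config$traits, components,
                                  population = "population")

  pops <- unique(tab$population)
  opportunity_tests <- list()
  if (length(pops) >= 2) {
    for (comp in components) {
      w_all <- unlist(lapply(pops, function(p) {
        v <- tab[[comp]][tab$population == p]
        relativize_fitness(v)
      }))
      g <- unlist(lapply(pops, function(p)
        rep(p, sum(tab$population == p))))
      ok <- !is.na(w_all)
      opportunity_tests[[comp]] <- brown_forsythe_test(w_all[ok], g = g[ok])
    }
  }

  # ---- path analysis ----
  sem_vars <- config$sem_variables
  rescale <- if (config$rescale_fitness &&
                 "seeds_per_plant" %in% sem_vars)
    c(seeds_per_plant = 1e-3) else NULL
  candidates <- enumerate_near_saturated(sem_vars, config$sem_exogenous,
                                         df_set = config$df_set)
  sem <- list()
  for (i in seq_along(pops)) {
    pop <- pops[i]
    sub <- tab[tab$population == pop, , drop = FALSE]
    ranking <- rank_candidates(candidates, sub, rescale = rescale)
    best_idx <- order(round(ranking$AIC, 10), round(ranking$BIC, 10))[1]
    best <- candidates[[best_idx]]
    trimmed <- trim_model(sub, best, alpha = config$alpha, engine = "ols",
                          rescale = rescale)
    boot <- bootstrap_path(trimmed$model, sub, B = config$bootstrap_B,
                           seed = config$seed + 1000 + i, rescale = rescale)
    ind <- if (all(c("corolla_color", "seeds_per_plant") %in% sem_vars))
      indirect_effects(trimmed$fit, "corolla_color", "seeds_per_plant",
                       boot = boot) else NULL
    sem[[pop]] <- list(ranking = ranking, best_index = best_idx,
                       best_model = best, trimmed = trimmed,
                       bootstrap = boot, indirect = ind)
  }

  bundle <- structure(list(
    config = config, seed = config$seed,
    package_version = as.character(utils::packageVersion("florsel")),
    table = tab, summaries = summaries, selection = selection,
    opportunity_tests = opportunity_tests, sem = sem),
    class = "report_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Analysis report bundle (seed", x$seed, ")\n")
  cat("  plants:", nrow(x$table), "in",
      length(unique(x$table$population)), "population(s)\n")
  cat("  fitness components:",
      paste(intersect(x$config$components, names(x$table)), collapse = ", "),
      "\n")
  for (pop in names(x$sem)) {
    tf <- x$sem[[pop]]$trimmed$fit
    cat(sprintf("  %s: best path model T = %.3f (df = %d), AIC = %.2f\n",
                pop, tf$T, tf$df, tf$AIC))
  }
  invisible(x)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  header <- sprintf("# florsel %s | seed %s", bundle$package_version,
                    format(bundle$seed))
  write_tsv <- function(df, file) {
    path <- file.path(out_dir, file)
    con <- file(path, "w")
    writeLines(header, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  write_tsv(bundle$summaries, "population_summaries.tsv")
  write_selection_table(bundle$selection,
                        file.path(out_dir, "selection_table.tsv"))
  for (pop in names(bundle$sem)) {
    sm <- bundle$sem[[pop]]
    fit <- sm$trimmed$fit
    jsonlite::write_json(list(
      population = pop,
      edges = paste0(fit$model$edges$from, "->", fit$model$edges$to),
      coefficients = as.list(fit$coef),
      standardized = standardized_solution(fit),
      T = fit$T, df = fit$df, AIC = fit$AIC, BIC = fit$BIC, R2 = as.list(fit$R2),
      bootstrap = sm$bootstrap$table,
      indirect = sm$indirect$inference),
      file.path(out_dir, paste0("path_model_", gsub("[^A-Za-z0-9_-]", "_", pop),
                                ".json")),
      auto_unbox = TRUE, digits = NA)
    write_tsv(sm$trimmed$steps,
              paste0("trimming_", gsub("[^A-Za-z0-9_-]", "_", pop), ".tsv"))
  }
  writeLines(c(header, utils::capture.output(utils::str(bundle$config))),
             file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
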
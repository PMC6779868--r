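# tiny FNV-1a hash of a deparsed R object, for run provenance lines
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- ((h + b) * 16777619) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Screen one histogram: detect peaks, assign roles, classify the quotient
#'
#' @param h An `fcss_histogram`.
#' @param scenarios Scenario set for classification.
#' @param params Peak parameters, see [peak_params()].
#' @param rel_tolerance Quotient-matching tolerance.
#' @return A list with `seed` (the `fcss_seed` measurement) and `call`
#'   (an `fcss_mode_call`, or the string `"no_endosperm"`).
#' @export
screen_histogram <- function(h, scenarios = enumerate_scenarios(2),
                             params = peak_params(), rel_tolerance = 0.08) {
  peaks <- detect_peaks(h, params)
  seed <- assign_roles(peaks, h, params)
  call <- if (seed$no_endosperm) "no_endosperm"
          else classify_quotient(seed$quotient, scenarios, rel_tolerance)
  list(seed = seed, call = call)
}

#' Run the full seed screen
#'
#' Orchestrates simulate (or read) -> peak detection -> role assignment ->
#' quotient classification -> species aggregation. Per-sample failures are
#' logged and skipped, never silently dropped. Deterministic for a fixed
#' config and seed.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{simulate}{a `species_config` list for
#'       [simulate_seed_set()] (mutually exclusive with `input_files`)}
#'     \item{input_files}{character vector of histogram files for
#'       [read_histogram()]}
#'     \item{scenario_options}{named list (by species) of argument lists
#'       for [enumerate_scenarios()]; the `default` entry applies to
#'       unlisted species (default: the standard diploid set)}
#'     \item{tolerance}{quotient-matching tolerance, default 0.08}
#'     \item{peak_params}{see [peak_params()]}
#'     \item{rng_seed}{integer seed, default 1}
#'     \item{output_dir}{optional; write calls.csv, species_summary.csv
#'       and run.log there}
#'   }
#' @return A list with `calls` (per-seed data.frame: sample_id, species,
#'   quotient, endosperm_percent, used_second_peak, mode, label,
#'   deviation), `species_summary` (species, n_seeds, per-mode counts,
#'   species_mode, mean endosperm percentage), `log` (character), and
#'   `config_hash`.
#' @export
run_screen <- function(config) {
  stopifnot(is.list(config))
  tol <- config$tolerance %||% 0.08
  params <- config$peak_params %||% peak_params()
  rng_seed <- config$rng_seed %||% 1L
  hash <- config_hash(config[setdiff(names(config), "output_dir")])
  log <- c(sprintf("config_hash: %s", hash),
           sprintf("rng_seed: %d", rng_seed),
           sprintf("tolerance: %g", tol),
           sprintf("min_particles: %g; max_cv: %g; quotient_range: [%g, %g]",
                   params$min_particles, params$max_cv,
                   params$valid_quotient_range[1L],
                   params$valid_quotient_range[2L]))

  if (!is.null(config$simulate)) {
    simset <- simulate_seed_set(config$simulate, rng_seed = rng_seed)
    hists <- lapply(simset$histograms, `[[`, "histogram")
    log <- c(log, sprintf("simulated %d seed histograms", length(hists)))
  } else if (!is.null(config$input_files)) {
    missing <- config$input_files[!file.exists(config$input_files)]
    if (length(missing)) {
      stop("input file(s) not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    hists <- lapply(config$input_files, read_histogram)
    log <- c(log, sprintf("read %d histogram files", length(hists)))
  } else {
    stop("config must provide either 'simulate' or 'input_files'",
         call. = FALSE)
  }

  scen_opts <- config$scenario_options %||% list()
  scen_cache <- new.env(parent = emptyenv())
  scenarios_for <- function(species) {
    key <- if (!is.null(scen_opts[[species]])) species else "default"
    if (is.null(scen_cache[[key]])) {
      opts <- scen_opts[[key]] %||% list(maternal_ploidy = 2)
      scen_cache[[key]] <- do.call(enumerate_scenarios, opts)
    }
    scen_cache[[key]]
  }

  rows <- list()
  calls_by_species <- list()
  for (h in hists) {
    res <- tryCatch(
      withCallingHandlers(
        screen_histogram(h, scenarios_for(h$species %||% "default"),
                         params, tol),
        warning = function(w) {
          log <<- c(log, sprintf("warning [%s]: %s", h$sample_id,
                                 conditionMessage(w)))
          invokeRestart("muffleWarning")
        }),
      error = function(e) e)
    if (inherits(res, "error")) {
      log <- c(log, sprintf("skipped [%s]: %s", h$sample_id,
                            conditionMessage(res)))
      next
    }
    seed <- res$seed
    for (nt in seed$notes) {
      log <- c(log, sprintf("note [%s]: %s", h$sample_id, nt))
    }
    is_ne <- identical(res$call, "no_endosperm")
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = seed$sample_id,
      species = seed$species %||% NA_character_,
      quotient = seed$quotient,
      endosperm_percent = seed$endosperm_percent,
      used_second_peak = seed$used_second_peak,
      mode = if (is_ne) "no_endosperm" else res$call$mode,
      label = if (is_ne) NA_character_ else res$call$label,
      deviation = if (is_ne) NA_real_ else res$call$deviation,
      stringsAsFactors = FALSE)
    sp <- seed$species %||% NA_character_
    if (is.na(sp)) sp <- "unknown"
    calls_by_species[[sp]] <- c(calls_by_species[[sp]], list(res$call))
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(0))

  summ <- lapply(names(calls_by_species), function(sp) {
    ag <- aggregate_species(calls_by_species[[sp]], species = sp)
    pct <- calls$endosperm_percent[calls$species == sp]
    data.frame(species = sp, n_seeds = ag$n_seeds,
               t(ag$mode_counts),
               species_mode = ag$species_mode,
               mean_endosperm_percent = mean(pct, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  species_summary <- if (length(summ)) do.call(rbind, summ) else
    data.frame(species = character(0))
  n_modes <- table(factor(species_summary$species_mode,
                          levels = c("sexual", "apomict",
                                     "facultative_apomict", "no_endosperm",
                                     "unresolved")))
  log <- c(log, sprintf(
    "species: %d sexual, %d apomict, %d facultative, %d no_endosperm, %d unresolved",
    n_modes[["sexual"]], n_modes[["apomict"]],
    n_modes[["facultative_apomict"]], n_modes[["no_endosperm"]],
    n_modes[["unresolved"]]))

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(calls, file.path(config$output_dir, "calls.csv"),
                     row.names = FALSE)
    utils::write.csv(species_summary,
                     file.path(config$output_dir, "species_summary.csv"),
                     row.names = FALSE)
    writeLines(log, file.path(config$output_dir, "run.log"))
  }
  list(calls = calls, species_summary = species_summary, log = log,
       config_hash = hash)
}

#' Compare apomict and sexual trait syndromes
#'
#' Runs the all-traits redundancy analysis followed by one analysis per
#' trait group, each with a Monte Carlo permutation test of the pseudo-F,
#' plus the per-trait univariate summary.
#'
#' @param config List with `n_permutations` (default 9999), `rng_seed`
#'   (default 1), optional `output_dir`.
#' @param traits Data.frame with `species`, trait columns and either a
#'   `mode_label` column or `mode_table` given.
#' @param mode_table Optional data.frame `species`, `species_mode` (as from
#'   [run_screen()]`$species_summary`); species called `apomict` or
#'   `facultative_apomict` are labeled apomicts, `no_endosperm` and
#'   `unresolved` species are dropped.
#' @param trait_groups Named list of trait column subsets; defaults to the
#'   `trait_groups` attribute of `traits`.
#' @return A list with `rda` (data.frame: one row for all traits plus one
#'   per group: pseudo_F, p_value, variance_explained, n_permutations),
#'   `table1` (the univariate summary), `log`, `config_hash`.
#' @export
run_compare <- function(config = list(), traits, mode_table = NULL,
                        trait_groups = attr(traits, "trait_groups")) {
  n_perm <- config$n_permutations %||% 9999L
  rng_seed <- config$rng_seed %||% 1L
  hash <- config_hash(list(config[setdiff(names(config), "output_dir")],
                           names(traits)))

  if (!("mode_label" %in% names(traits))) {
    if (is.null(mode_table)) {
      stop("traits has no mode_label column and no mode_table given",
           call. = FALSE)
    }
    missing <- setdiff(traits$species, mode_table$species)
    if (length(missing)) {
      stop("species missing from mode table: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    sm <- mode_table$species_mode[match(traits$species, mode_table$species)]
    keep <- sm %in% c("sexual", "apomict", "facultative_apomict")
    traits <- traits[keep, , drop = FALSE]
    traits$mode_label <- ifelse(sm[keep] == "sexual", "non_apomict",
                                "apomict")
  }
  if (is.null(trait_groups)) {
    trait_groups <- list(all_traits = setdiff(names(traits),
                                              c("species", "mode_label")))
    run_all <- FALSE
  } else {
    run_all <- TRUE
  }
  x <- traits$mode_label
  groups <- trait_groups
  if (run_all) {
    groups <- c(list(all = unlist(trait_groups, use.names = FALSE)), groups)
  }
  seeds <- with_seed(rng_seed,
                     sample.int(.Machine$integer.max - 1L, length(groups)))
  rows <- lapply(seq_along(groups), function(i) {
    cols <- intersect(groups[[i]], names(traits))
    r <- permutation_test(traits[, cols, drop = FALSE], x,
                          n_perm = n_perm, rng_seed = seeds[[i]])
    data.frame(trait_group = names(groups)[[i]], n_traits = length(cols),
               pseudo_F = r$pseudo_F, p_value = r$p_value,
               variance_explained = r$variance_explained,
               n_permutations = r$n_permutations,
               stringsAsFactors = FALSE)
  })
  rda <- do.call(rbind, rows)
  tab1 <- table1_summary(traits, rng_seed = rng_seed)
  log <- c(sprintf("config_hash: %s", hash),
           sprintf("rng_seed: %d", rng_seed),
           sprintf("n_permutations: %d", n_perm),
           sprintf("n_species: %d (%d apomicts)", nrow(traits),
                   sum(traits$mode_label == "apomict")))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rda, file.path(config$output_dir, "rda_results.csv"),
                     row.names = FALSE)
    utils::write.csv(tab1, file.path(config$output_dir, "trait_summary.csv"),
                     row.names = FALSE)
    writeLines(log, file.path(config$output_dir, "compare.log"))
  }
  list(rda = rda, table1 = tab1, log = log, config_hash = hash)
}
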
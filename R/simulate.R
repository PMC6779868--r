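# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configure one simulated seed sample
#'
#' Describes the DAPI-stained seed histogram to simulate: a Gaussian
#' embryo G0/G1 peak, an endosperm G1 peak at the scenario's expected
#' quotient times the embryo position, optional G2 replicate peaks at
#' exactly twice each G1 position, an optional internal-standard peak,
#' and exponentially decaying debris. Component counts are expressed as
#' fractions of the embryo count; the defaults mirror a typical seed run
#' (at least 5000 recorded particles, endosperm nuclei roughly 40\% of
#' the embryo count, G2 replicates at 10\%, moderate debris).
#'
#' Under `endopolyploid = TRUE` the endosperm G1 peak is suppressed and
#' only a weak replicate peak at twice the expected endosperm position is
#' produced, emulating taxa where strong endopolyploidy hides the
#' endosperm G1 signal.
#'
#' @param scenario A profile label (e.g. `"2/5"`) or an `fcss_scenario`.
#' @param maternal_ploidy Used to resolve a label to a scenario (default 2).
#' @param embryo_position Embryo G1 mean fluorescence (channels), default 100.
#' @param cv Coefficient of variation of every peak (\%), default 3.
#' @param total_particles Total recorded events, default 5000.
#' @param endosperm_frac Endosperm:embryo nuclei count ratio, default 0.4.
#' @param g2,g2_frac Simulate G2 replicate peaks (default on) at this
#'   fraction of the parent G1 count (default 0.1).
#' @param endopolyploid,endopolyploid_frac Endopolyploidy mode (see above);
#'   the replicate peak gets this fraction of the embryo count (0.12).
#' @param debris_frac Fraction of events that are debris, default 0.2.
#' @param debris_scale Exponential decay constant of debris (channels), 20.
#' @param standard Optional list(species, two_c_pg, position) for an
#'   internal standard peak.
#' @param standard_frac Standard count as fraction of embryo count, 0.15.
#' @param n_channels Number of linear channels, default 1024.
#' @param seeds_pooled,species,sample_id Metadata passed through.
#' @return A list of class `fcss_seed_sim`.
#' @export
seed_sim <- function(scenario = "2/3",
                     maternal_ploidy = 2,
                     embryo_position = 100,
                     cv = 3,
                     total_particles = 5000L,
                     endosperm_frac = 0.4,
                     g2 = TRUE, g2_frac = 0.1,
                     endopolyploid = FALSE, endopolyploid_frac = 0.12,
                     debris_frac = 0.2, debris_scale = 20,
                     standard = NULL, standard_frac = 0.15,
                     n_channels = 1024L,
                     seeds_pooled = 1L,
                     species = NA_character_,
                     sample_id = "sim") {
  stopifnot(embryo_position > 0, cv > 0, cv <= 25,
            total_particles >= 1, seeds_pooled >= 1,
            debris_scale > 0, debris_frac >= 0, debris_frac < 1)
  sc <- if (inherits(scenario, "fcss_scenario")) scenario
        else resolve_scenario(scenario, maternal_ploidy)
  structure(list(scenario = sc, embryo_position = embryo_position, cv = cv,
                 total_particles = as.integer(total_particles),
                 endosperm_frac = endosperm_frac,
                 g2 = g2, g2_frac = g2_frac,
                 endopolyploid = endopolyploid,
                 endopolyploid_frac = endopolyploid_frac,
                 debris_frac = debris_frac, debris_scale = debris_scale,
                 standard = standard, standard_frac = standard_frac,
                 n_channels = as.integer(n_channels),
                 seeds_pooled = as.integer(seeds_pooled),
                 species = species, sample_id = sample_id),
            class = "fcss_seed_sim")
}

#' Resolve a profile label to a scenario
#'
#' Searches the fully extended scenario set for the given maternal ploidy
#' (tri-nucleate central cells, BIII hybrids and all sperm combinations
#' enabled, self- and diploid pollen) for a scenario whose profile label
#' matches. Labels are embryo-first (`"2/5"`); the endosperm-first order
#' is accepted too.
#'
#' @param label Profile label.
#' @param maternal_ploidy Maternal ploidy in x.
#' @return An `fcss_scenario`.
#' @export
resolve_scenario <- function(label, maternal_ploidy = 2) {
  prof <- parse_profile(label)
  pool <- enumerate_scenarios(maternal_ploidy,
                              pollen_ploidies = unique(c(maternal_ploidy, 2)),
                              trinucleate = TRUE, biii = TRUE,
                              all_sperm_combos = TRUE)
  for (sc in pool) {
    cv <- expected_c_values(sc)
    if (abs(cv$embryo_C - prof$embryo_C) < 1e-9 &&
        abs(cv$endosperm_C - prof$endosperm_C) < 1e-9) return(sc)
  }
  stop("no scenario with profile '", label, "' for maternal ploidy ",
       maternal_ploidy, call. = FALSE)
}

#' Simulate one FCSS histogram with known ground truth
#'
#' Draws `total_particles` events from a mixture of Gaussian peaks and
#' exponential debris, bins them on a linear channel axis, and returns the
#' histogram together with a truth record of every simulated peak. The
#' histogram total equals `total_particles` exactly (out-of-range events
#' are clamped into the edge channels); the same seed reproduces the same
#' histogram bit for bit.
#'
#' @param sim An `fcss_seed_sim` from [seed_sim()].
#' @param rng_seed Integer seed.
#' @return A list with `histogram` (`fcss_histogram`), `truth` (data.frame
#'   of simulated peaks: role, position, cv, expected count), `scenario`,
#'   `quotient_truth`, `mode_truth`.
#' @export
#' @examples
#' s <- simulate_histogram(seed_sim("2/5"), rng_seed = 1)
#' sum(s$histogram$counts)   # exactly 5000
simulate_histogram <- function(sim, rng_seed) {
  stopifnot(inherits(sim, "fcss_seed_sim"))
  if (sim$total_particles < 1) stop("zero particles requested", call. = FALSE)
  prof <- expected_c_values(sim$scenario)
  q <- prof$quotient
  pos_e <- sim$embryo_position
  pos_s <- q * pos_e

  comp <- list(list(role = "embryo_G1", pos = pos_e, w = 1))
  if (sim$g2) {
    comp <- c(comp, list(list(role = "embryo_G2", pos = 2 * pos_e,
                              w = sim$g2_frac)))
  }
  if (sim$endopolyploid) {
    comp <- c(comp, list(list(role = "endosperm_replicate", pos = 2 * pos_s,
                              w = sim$endopolyploid_frac)))
  } else {
    comp <- c(comp, list(list(role = "endosperm_G1", pos = pos_s,
                              w = sim$endosperm_frac)))
    if (sim$g2) {
      comp <- c(comp, list(list(role = "endosperm_replicate", pos = 2 * pos_s,
                                w = sim$endosperm_frac * sim$g2_frac)))
    }
  }
  if (!is.null(sim$standard)) {
    comp <- c(comp, list(list(role = "standard", pos = sim$standard$position,
                              w = sim$standard_frac)))
  }
  w <- vapply(comp, `[[`, numeric(1L), "w")
  pos <- vapply(comp, `[[`, numeric(1L), "pos")
  role <- vapply(comp, `[[`, character(1L), "role")
  probs <- c(w / sum(w) * (1 - sim$debris_frac), sim$debris_frac)

  counts <- with_seed(rng_seed, {
    ci <- sample.int(length(probs), sim$total_particles, replace = TRUE,
                     prob = probs)
    v <- numeric(sim$total_particles)
    for (j in seq_along(comp)) {
      sel <- ci == j
      v[sel] <- stats::rnorm(sum(sel), mean = pos[j],
                             sd = sim$cv / 100 * pos[j])
    }
    deb <- ci == length(probs)
    v[deb] <- stats::rexp(sum(deb), rate = 1 / sim$debris_scale)
    bins <- pmin(pmax(round(v), 1L), sim$n_channels)
    tabulate(bins, nbins = sim$n_channels)
  })

  h <- fcss_histogram(
    channels = seq_len(sim$n_channels), counts = counts,
    sample_id = sim$sample_id, species = sim$species,
    seeds_pooled = sim$seeds_pooled,
    standard_species = if (is.null(sim$standard)) NA_character_
                       else sim$standard$species,
    standard_2C_pg = if (is.null(sim$standard)) NA_real_
                     else sim$standard$two_c_pg)
  truth <- data.frame(role = role, position = pos, cv = sim$cv,
                      expected_count = sim$total_particles *
                        probs[seq_along(comp)],
                      stringsAsFactors = FALSE)
  list(histogram = h, truth = truth, scenario = sim$scenario,
       quotient_truth = q, mode_truth = sim$scenario$mode)
}

#' Simulate a set of seeds across species with known per-seed truth
#'
#' Each species gets an exact number of seeds per scenario: proportions
#' are converted to counts by largest-remainder rounding and the seed
#' order is then shuffled, so e.g. a 20:2 sexual:apomictic mix of 22 seeds
#' yields exactly two apomictic seeds in every run.
#'
#' @param species_config A list; each element a list with `species`,
#'   `mix` (named proportions, names are profile labels, summing to 1),
#'   `n_seeds`, optional `maternal_ploidy` and further [seed_sim()]
#'   arguments.
#' @param rng_seed Integer seed.
#' @return A list with `histograms` (list of [simulate_histogram()]
#'   results) and `truth` (data.frame: sample_id, species, label,
#'   mode_truth, quotient_truth).
#' @export
simulate_seed_set <- function(species_config, rng_seed) {
  if (length(species_config) == 0L) stop("empty species_config", call. = FALSE)
  plan <- list()
  for (cfgi in seq_along(species_config)) {
    cfg <- species_config[[cfgi]]
    stopifnot(!is.null(cfg$species), !is.null(cfg$mix), !is.null(cfg$n_seeds))
    p <- cfg$mix
    if (abs(sum(p) - 1) > 1e-8) {
      stop("scenario mix proportions must sum to 1 for species ",
           cfg$species, call. = FALSE)
    }
    n <- cfg$n_seeds
    base <- floor(p * n)
    rem <- n - sum(base)
    if (rem > 0) {
      fr <- p * n - base
      add <- order(fr, decreasing = TRUE)[seq_len(rem)]
      base[add] <- base[add] + 1L
    }
    labels <- rep(names(p), times = base)
    plan[[cfgi]] <- list(cfg = cfg, labels = labels)
  }

  n_total <- sum(vapply(plan, function(x) length(x$labels), integer(1L)))
  draws <- with_seed(rng_seed, {
    list(order = lapply(plan, function(x) sample.int(length(x$labels))),
         seeds = sample.int(.Machine$integer.max - 1L, n_total))
  })

  histograms <- list()
  truth <- list()
  k <- 0L
  for (i in seq_along(plan)) {
    cfg <- plan[[i]]$cfg
    labels <- plan[[i]]$labels[draws$order[[i]]]
    m <- cfg$maternal_ploidy %||% 2
    extra <- cfg[setdiff(names(cfg),
                         c("species", "mix", "n_seeds", "maternal_ploidy"))]
    for (j in seq_along(labels)) {
      k <- k + 1L
      sid <- sprintf("%s_seed%03d", gsub("\\s+", "_", cfg$species), j)
      args <- c(list(scenario = labels[[j]], maternal_ploidy = m,
                     species = cfg$species, sample_id = sid), extra)
      sim <- do.call(seed_sim, args)
      res <- simulate_histogram(sim, rng_seed = draws$seeds[[k]])
      histograms[[k]] <- res
      truth[[k]] <- data.frame(sample_id = sid, species = cfg$species,
                               label = labels[[j]],
                               mode_truth = res$mode_truth,
                               quotient_truth = res$quotient_truth,
                               stringsAsFactors = FALSE)
    }
  }
  list(histograms = histograms, truth = do.call(rbind, truth))
}

# default trait universe emulating a functional-trait table:
# continuous traits plus binary clonal-growth indicators, in four groups
default_trait_groups <- function() {
  list(
    whole_plant = c("plant_height"),
    organ = c("leaf_N", "leaf_P", "leaf_dry_matter"),
    clonal = c("clonal", "rhizome_short", "nonspreading_integrator",
               "nonspreading_splitter"),
    ecological = c("moisture", "elevation_range", "landscape_abundance")
  )
}

default_binary_traits <- function() {
  c("clonal", "rhizome_short", "nonspreading_integrator",
    "nonspreading_splitter")
}

#' Configure a synthetic species x trait table
#'
#' Defaults emulate a screen-scale dataset: 220 species with mode calls of
#' which a small minority are apomicts, continuous traits on a
#' standardized scale and binary clonal-growth indicators. Effects are
#' specified per trait: a standardized mean shift (apomicts minus sexuals)
#' for continuous traits, or a length-2 vector of group probabilities
#' c(apomict, sexual) for binary traits. The default effects encode the
#' clonality contrast observed in real screens (clonal in ~85\% of
#' apomicts vs ~33\% of sexuals) and moderate moisture/range shifts; all
#' other traits are null.
#'
#' @param n_species Number of species (>= 4), default 220.
#' @param apomict_fraction Proportion of apomicts in (0,1), default 13/220.
#' @param effects Named list of per-trait effects (see above). Unknown
#'   trait names are an error.
#' @param noise_sd Within-group standard deviation of continuous traits.
#' @param rng_seed Integer seed.
#' @return A list of class `fcss_trait_sim_config`.
#' @export
trait_sim_config <- function(n_species = 220L,
                             apomict_fraction = 13 / 220,
                             effects = list(clonal = c(0.85, 0.33),
                                            moisture = 0.5,
                                            elevation_range = 0.5),
                             noise_sd = 1,
                             rng_seed = 1L) {
  stopifnot(n_species >= 4, apomict_fraction > 0, apomict_fraction < 1,
            noise_sd > 0)
  groups <- default_trait_groups()
  all_traits <- unlist(groups, use.names = FALSE)
  unknown <- setdiff(names(effects), all_traits)
  if (length(unknown)) {
    stop("effect specified for unknown trait(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n_apo <- round(n_species * apomict_fraction)
  n_apo <- min(max(n_apo, 1L), n_species - 1L)
  structure(list(n_species = as.integer(n_species),
                 n_apomicts = as.integer(n_apo),
                 effects = effects, noise_sd = noise_sd,
                 rng_seed = as.integer(rng_seed),
                 trait_groups = groups,
                 binary_traits = default_binary_traits()),
            class = "fcss_trait_sim_config")
}

#' Simulate a species x trait table with known group effects
#'
#' @param cfg An `fcss_trait_sim_config`.
#' @return A data.frame with columns `species`, `mode_label`
#'   (`"apomict"` / `"non_apomict"`) and one column per trait; attributes
#'   `trait_groups` (named list of column subsets) and `truth` (the effect
#'   list used).
#' @export
simulate_trait_table <- function(cfg) {
  stopifnot(inherits(cfg, "fcss_trait_sim_config"))
  n <- cfg$n_species
  n_apo <- cfg$n_apomicts
  mode_label <- c(rep("apomict", n_apo), rep("non_apomict", n - n_apo))
  all_traits <- unlist(cfg$trait_groups, use.names = FALSE)
  binary <- cfg$binary_traits

  tab <- with_seed(cfg$rng_seed, {
    cols <- lapply(all_traits, function(tr) {
      eff <- cfg$effects[[tr]]
      if (tr %in% binary) {
        p <- if (is.null(eff)) c(0.3, 0.3) else eff
        stopifnot(length(p) == 2L, all(p >= 0), all(p <= 1))
        stats::rbinom(n, 1L, ifelse(mode_label == "apomict", p[[1L]], p[[2L]]))
      } else {
        shift <- if (is.null(eff)) 0 else eff
        stopifnot(length(shift) == 1L)
        mu <- ifelse(mode_label == "apomict", shift * cfg$noise_sd, 0)
        stats::rnorm(n, mean = mu, sd = cfg$noise_sd)
      }
    })
    names(cols) <- all_traits
    cols
  })
  out <- data.frame(species = sprintf("sp%03d", seq_len(n)),
                    mode_label = mode_label, tab,
                    stringsAsFactors = FALSE)
  attr(out, "trait_groups") <- cfg$trait_groups
  attr(out, "truth") <- cfg$effects
  out
}
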
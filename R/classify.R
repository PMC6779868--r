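#' Classify an observed endosperm:embryo quotient into a reproductive mode
#'
#' Matches the observed quotient (mean endosperm fluorescence divided by
#' mean embryo fluorescence) against the expected quotients of a scenario
#' set. All scenarios tying for the minimal relative deviation are kept; if
#' the minimal deviation exceeds the tolerance the call is `unresolved`
#' rather than force-fitted to the nearest scenario (unexplained quotients
#' do occur in real screens and deserve to stay unexplained).
#'
#' When tied scenarios belong to different mode classes (a C-value quotient
#' alone cannot, e.g., separate a sexual 2/3 seed from a BIII 4/6 seed),
#' the reported mode follows a parsimony preference
#' sexual > pseudogamous > autonomous > BIII hybrid, and the full tie is
#' retained in `matched_scenarios` for audit.
#'
#' @param observed Observed quotient (> 0).
#' @param scenarios A list of `fcss_scenario`, e.g. from
#'   [enumerate_scenarios()].
#' @param rel_tolerance Maximal relative deviation |observed - expected| /
#'   expected for a match. The default 0.08 cleanly separates the default
#'   diploid quotients (1.5, 2.0, 2.5, 3.0, adjacent pairs differing by
#'   20\% or more).
#' @return An `fcss_mode_call`: `observed_quotient`, `matched_scenarios`,
#'   `mode` (one of sexual, apomictic_pseudogamous, apomictic_autonomous,
#'   BIII_hybrid, unresolved), `label`, `deviation`, `tolerance`.
#' @export
#' @examples
#' sc <- enumerate_scenarios(2, trinucleate = TRUE)
#' classify_quotient(3.32, sc)   # matches the 2/7 profile
classify_quotient <- function(observed, scenarios, rel_tolerance = 0.08) {
  stopifnot(is.numeric(observed), length(observed) == 1L, observed > 0,
            length(scenarios) > 0, rel_tolerance > 0)
  expq <- vapply(scenarios, function(s) expected_c_values(s)$quotient,
                 numeric(1L))
  dev <- abs(observed - expq) / expq
  dmin <- min(dev)
  if (dmin > rel_tolerance) {
    matched <- list()
    mode <- "unresolved"
    label <- NA_character_
    dmin_out <- NA_real_
  } else {
    matched <- scenarios[dev <= dmin + 1e-9]
    classes <- vapply(matched, `[[`, character(1L), "mode")
    pref <- c("sexual", "apomictic_pseudogamous", "apomictic_autonomous",
              "BIII_hybrid")
    mode <- pref[min(match(classes, pref))]
    label <- unique(vapply(matched, `[[`, character(1L), "label"))[1L]
    dmin_out <- dmin
  }
  structure(list(observed_quotient = observed,
                 matched_scenarios = matched,
                 mode = mode,
                 label = label,
                 deviation = dmin_out,
                 tolerance = rel_tolerance),
            class = "fcss_mode_call")
}

#' @export
print.fcss_mode_call <- function(x, ...) {
  if (x$mode == "unresolved") {
    cat(sprintf("FCSS call: quotient %.3f -> unresolved (no scenario within %g%%)\n",
                x$observed_quotient, 100 * x$tolerance))
  } else {
    cat(sprintf("FCSS call: quotient %.3f -> %s (profile %s, deviation %.2f%%, %d matched)\n",
                x$observed_quotient, x$mode, x$label, 100 * x$deviation,
                length(x$matched_scenarios)))
  }
  invisible(x)
}

#' Summarize per-seed mode calls for one species
#'
#' A species is called apomictic when at least one seed shows an apomictic
#' profile, and facultatively apomictic when sexual and apomictic seeds
#' co-occur (as in grasses where 20 of 22 seeds may be sexual and two
#' pseudogamous). Species whose every sample lacked an endosperm signal are
#' flagged and excluded from mode inference.
#'
#' @param calls A list of `fcss_mode_call` (and/or the string
#'   `"no_endosperm"` for samples without an endosperm peak) for one
#'   species.
#' @param species Optional species name carried into the summary.
#' @return A list with `species`, `n_seeds`, `mode_counts` (named integer
#'   vector over all mode classes), and `species_mode`: one of `"sexual"`,
#'   `"apomict"`, `"facultative_apomict"`, `"no_endosperm"`,
#'   `"unresolved"`.
#' @export
aggregate_species <- function(calls, species = NA_character_) {
  stopifnot(length(calls) >= 1L)
  modes <- vapply(calls, function(cl) {
    if (is.character(cl)) cl else cl$mode
  }, character(1L))
  levels <- c("sexual", "apomictic_pseudogamous", "apomictic_autonomous",
              "BIII_hybrid", "unresolved", "no_endosperm")
  bad <- setdiff(unique(modes), levels)
  if (length(bad)) stop("unknown mode label(s): ", paste(bad, collapse = ", "))
  counts <- vapply(levels, function(l) sum(modes == l), integer(1L))
  n_apo <- sum(counts[c("apomictic_pseudogamous", "apomictic_autonomous",
                        "BIII_hybrid")])
  n_sex <- counts[["sexual"]]
  species_mode <- if (counts[["no_endosperm"]] == length(modes)) {
    "no_endosperm"
  } else if (n_apo > 0 && n_sex > 0) {
    "facultative_apomict"
  } else if (n_apo > 0) {
    "apomict"
  } else if (n_sex > 0) {
    "sexual"
  } else {
    "unresolved"
  }
  list(species = species, n_seeds = length(modes), mode_counts = counts,
       species_mode = species_mode)
}

#' Back-calculate gamete genome sizes under each scenario
#'
#' Given absolute genome sizes (pg, from internal-standard calibration) of
#' the embryo and the endosperm of one seed, solves each candidate scenario
#' for the genome sizes of the gametes it implies: the per-nucleus polar
#' contribution and, where sperm are involved, the sperm genome size. The
#' most likely scenario is the one under which every implied gamete genome
#' size is close to the embryo genome size (unreduced gametes) or to half
#' of it (reduced gametes); scenarios tying for consistency are returned as
#' alternates, since e.g. one unreduced sperm and two reduced sperms
#' produce identical endosperm DNA amounts. (For scenarios with a
#' fertilized embryo the comparison reference is the implied maternal
#' somatic genome size, which coincides with the embryo genome size in
#' every parthenogenetic scenario.)
#'
#' The linear system per scenario (u = maternal genome size per x,
#' v = sperm genome size):
#' \deqn{embryo = eggC \cdot u + f \cdot v, \quad
#'       endosperm = k \cdot polarC \cdot u + s \cdot v}
#' with f = 1 for a fertilized embryo. Parthenogenetic scenarios fix u from
#' the embryo alone.
#'
#' @param embryo_gs_pg,endosperm_gs_pg Absolute genome sizes in pg (> 0).
#' @param scenarios Candidate scenario list.
#' @param rel_tolerance Relative closeness required of each implied gamete
#'   to its target (embryo or embryo/2); default 0.10.
#' @return A list of solutions, ranked by deviation, each with `scenario`,
#'   `implied_sperm_gs`, `implied_polar_sum_gs`, `consistency`
#'   (`reduced_consistent`, `unreduced_consistent`, `inconsistent`),
#'   `deviation`, and `alternates` (indices of equally consistent
#'   solutions, on the first element).
#' @export
#' @examples
#' sc <- enumerate_scenarios(2)
#' sol <- gamete_backcalc(2.0, 5.0, sc)
#' sol[[1]]$scenario$label            # "2/5"
#' sol[[1]]$implied_sperm_gs          # 1.0 pg = embryo / 2
gamete_backcalc <- function(embryo_gs_pg, endosperm_gs_pg, scenarios,
                            rel_tolerance = 0.10) {
  stopifnot(embryo_gs_pg > 0, endosperm_gs_pg > 0, length(scenarios) > 0)
  sols <- lapply(scenarios, function(sc) {
    egg_C <- if (sc$egg_reduced) sc$maternal_ploidy / 2 else sc$maternal_ploidy
    polar_C <- if (sc$polar_reduced) sc$maternal_ploidy / 2 else sc$maternal_ploidy
    k <- sc$polar_nuclei
    s <- sc$endosperm_sperms
    f <- as.integer(sc$embryo_fertilized)

    u <- v <- NA_real_
    if (f == 0L) {
      u <- embryo_gs_pg / egg_C
      if (s > 0L) v <- (endosperm_gs_pg - k * polar_C * u) / s
    } else {
      A <- matrix(c(egg_C, k * polar_C, f, s), nrow = 2L)
      if (abs(det(A)) < 1e-12) {
        return(list(scenario = sc, implied_sperm_gs = NA_real_,
                    implied_polar_sum_gs = NA_real_,
                    consistency = "inconsistent", deviation = Inf))
      }
      uv <- solve(A, c(embryo_gs_pg, endosperm_gs_pg))
      u <- uv[[1L]]; v <- uv[[2L]]
    }
    polar_each <- polar_C * u
    polar_sum <- k * polar_each

    # reference for "unreduced gamete": the maternal somatic genome size
    # implied by the solve (m x u). For every parthenogenetic scenario this
    # equals the embryo genome size, which is the published comparison; for
    # fertilized embryos (sexual, BIII) the embryo additionally contains
    # the sperm, so the maternal reference is the coherent generalization.
    ref <- sc$maternal_ploidy * u
    gamete_dev <- function(gs, reduced) {
      target <- if (reduced) ref / 2 else ref
      abs(gs - target) / max(target, 1e-12)
    }
    devs <- gamete_dev(polar_each, sc$polar_reduced)
    any_sperm <- f == 1L || s > 0L
    if (any_sperm) devs <- c(devs, gamete_dev(v, sc$sperm_reduced))
    if (s == 0L) {
      # endosperm equation is not used in the solve; check its residual
      devs <- c(devs, abs(endosperm_gs_pg - k * polar_each) / endosperm_gs_pg)
    }
    positive <- u > 0 && (!any_sperm || v > 0)
    deviation <- max(devs)
    consistent <- positive && deviation <= rel_tolerance
    consistency <- if (!consistent) {
      "inconsistent"
    } else if (any_sperm) {
      if (sc$sperm_reduced) "reduced_consistent" else "unreduced_consistent"
    } else {
      if (sc$polar_reduced) "reduced_consistent" else "unreduced_consistent"
    }
    list(scenario = sc,
         implied_sperm_gs = if (any_sperm) v else NA_real_,
         implied_polar_sum_gs = polar_sum,
         consistency = consistency,
         deviation = deviation)
  })
  ord <- order(vapply(sols, `[[`, numeric(1L), "deviation"))
  sols <- sols[ord]
  best_dev <- sols[[1L]]$deviation
  ties <- which(vapply(sols, function(s) {
    s$consistency != "inconsistent" && s$deviation <= best_dev + 1e-9
  }, logical(1L)))
  sols[[1L]]$alternates <- setdiff(ties, 1L)
  sols
}
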
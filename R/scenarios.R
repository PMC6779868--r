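#' Fertilization / gametophyte-formation scenarios
#'
#' A scenario describes how one seed's embryo and endosperm were formed:
#' the maternal ploidy, whether the egg cell was meiotically reduced,
#' whether the embryo was fertilized, how many polar nuclei the central
#' cell contained (two normally, three in rare tri-nucleate sacs), and how
#' many sperm cells of what reduction state fertilized the endosperm.
#' From these the expected C-values of embryo and endosperm follow by
#' simple addition of gametic contributions, in multiples of the
#' monoploid (1x) genome.
#'
#' C-value bookkeeping (x units):
#' \itemize{
#'   \item egg C = m/2 if reduced, m if unreduced
#'   \item sperm C = p/2 if reduced, p if unreduced
#'   \item embryo C = egg C (+ one sperm C if the embryo is fertilized)
#'   \item endosperm C = k x polar C + s x sperm C
#' }
#' A sexual diploid seed therefore has a 2C embryo (1C egg + 1C sperm) and
#' 3C endosperm (two 1C polar nuclei + 1C sperm), quotient 1.5.
#'
#' @param maternal_ploidy Maternal ploidy m in multiples of x (>= 2 unless
#'   `allow_haploid`).
#' @param egg_reduced Logical; was the egg cell meiotically reduced?
#' @param embryo_fertilized Logical; did a sperm fuse with the egg?
#'   Reduced egg + fertilization is sexual reproduction; unreduced egg +
#'   fertilization is a BIII hybrid; unreduced egg without fertilization is
#'   parthenogenesis (apomixis).
#' @param polar_nuclei Number of polar nuclei k in the central cell (2 or 3).
#' @param polar_reduced Logical; polar nuclei reduced (sexual sacs) or
#'   unreduced (apomictic sacs)?
#' @param endosperm_sperms Number of sperm cells s fusing with the central
#'   cell (0 = autonomous endosperm, 1 or 2 = fertilized endosperm).
#' @param pollen_ploidy Ploidy p of the pollen donor in multiples of x;
#'   may be NA when no sperm is involved anywhere.
#' @param sperm_reduced Logical; sperm cells reduced (p/2) or unreduced (p)?
#' @param allow_haploid Permit m = 1 (off by default; haploid mothers are
#'   outside the standard screen).
#'
#' @return An object of class `fcss_scenario` with the fields above plus
#'   `mode`, one of `"sexual"`, `"apomictic_pseudogamous"`,
#'   `"apomictic_autonomous"`, `"BIII_hybrid"`.
#' @seealso [expected_c_values()], [enumerate_scenarios()],
#'   [classify_quotient()]
#' @export
#' @examples
#' sexual <- scenario_spec(2, egg_reduced = TRUE, embryo_fertilized = TRUE,
#'                         polar_reduced = TRUE, endosperm_sperms = 1,
#'                         pollen_ploidy = 2, sperm_reduced = TRUE)
#' expected_c_values(sexual)  # 2C embryo, 3C endosperm
scenario_spec <- function(maternal_ploidy,
                          egg_reduced,
                          embryo_fertilized,
                          polar_nuclei = 2L,
                          polar_reduced = egg_reduced,
                          endosperm_sperms = 1L,
                          pollen_ploidy = NA_real_,
                          sperm_reduced = NA,
                          allow_haploid = FALSE) {
  m <- maternal_ploidy
  stopifnot(is.numeric(m), length(m) == 1L, m >= 1)
  if (m < 2 && !allow_haploid) {
    stop("haploid maternal plants (m = 1) are outside the default screen; ",
         "set allow_haploid = TRUE to override", call. = FALSE)
  }
  stopifnot(isTRUE(egg_reduced) || isFALSE(egg_reduced),
            isTRUE(embryo_fertilized) || isFALSE(embryo_fertilized),
            polar_nuclei %in% c(2L, 3L),
            isTRUE(polar_reduced) || isFALSE(polar_reduced),
            endosperm_sperms %in% c(0L, 1L, 2L))
  if (egg_reduced && !embryo_fertilized) {
    stop("a reduced, unfertilized egg (polyhaploid parthenogenesis) is not ",
         "a recognized scenario", call. = FALSE)
  }
  needs_sperm <- embryo_fertilized || endosperm_sperms > 0L
  if (needs_sperm) {
    if (is.na(pollen_ploidy) || pollen_ploidy < 1) {
      stop("pollen_ploidy must be given (>= 1) when any sperm is involved",
           call. = FALSE)
    }
    if (is.na(sperm_reduced)) {
      stop("sperm_reduced must be given when any sperm is involved",
           call. = FALSE)
    }
  } else {
    pollen_ploidy <- NA_real_
    sperm_reduced <- NA
  }

  mode <- if (embryo_fertilized) {
    if (egg_reduced) "sexual" else "BIII_hybrid"
  } else {
    if (endosperm_sperms == 0L) "apomictic_autonomous"
    else "apomictic_pseudogamous"
  }

  sc <- structure(list(
    maternal_ploidy = as.numeric(m),
    egg_reduced = egg_reduced,
    embryo_fertilized = embryo_fertilized,
    polar_nuclei = as.integer(polar_nuclei),
    polar_reduced = polar_reduced,
    endosperm_sperms = as.integer(endosperm_sperms),
    pollen_ploidy = as.numeric(pollen_ploidy),
    sperm_reduced = sperm_reduced,
    mode = mode
  ), class = "fcss_scenario")
  prof <- expected_c_values(sc)
  if (prof$embryo_C <= 0 || prof$endosperm_C <= 0) {
    stop("scenario yields non-positive C-values", call. = FALSE)
  }
  sc$label <- prof$label
  sc
}

#' Expected embryo and endosperm C-values of a scenario
#'
#' @param sc An `fcss_scenario`.
#' @return A list with `embryo_C`, `endosperm_C` (multiples of x),
#'   `quotient` (endosperm C / embryo C) and the profile `label`
#'   ("embryo/endosperm", e.g. `"2/5"`).
#' @export
expected_c_values <- function(sc) {
  stopifnot(inherits(sc, "fcss_scenario"))
  egg_C <- if (sc$egg_reduced) sc$maternal_ploidy / 2 else sc$maternal_ploidy
  polar_C <- if (sc$polar_reduced) sc$maternal_ploidy / 2 else sc$maternal_ploidy
  sperm_C <- if (sc$embryo_fertilized || sc$endosperm_sperms > 0L) {
    if (sc$sperm_reduced) sc$pollen_ploidy / 2 else sc$pollen_ploidy
  } else 0
  embryo_C <- egg_C + if (sc$embryo_fertilized) sperm_C else 0
  endosperm_C <- sc$polar_nuclei * polar_C + sc$endosperm_sperms * sperm_C
  list(embryo_C = embryo_C,
       endosperm_C = endosperm_C,
       quotient = endosperm_C / embryo_C,
       label = format_profile(embryo_C, endosperm_C))
}

#' Format / parse embryo-endosperm profile labels
#'
#' Profiles are written embryo-first (`"2/5"`); the literature also uses the
#' endosperm-first order (`"5/2"`). `parse_profile()` accepts both and
#' normalizes on the fact that the endosperm C-value exceeds the embryo
#' C-value in every recognized scenario.
#'
#' @param embryo_C,endosperm_C C-values in x units.
#' @return `format_profile()`: a label string. `parse_profile()`: a list
#'   with `embryo_C`, `endosperm_C`, `quotient`.
#' @export
format_profile <- function(embryo_C, endosperm_C) {
  fmt <- function(v) {
    if (abs(v - round(v)) < 1e-9) as.character(round(v)) else format(v)
  }
  paste0(fmt(embryo_C), "/", fmt(endosperm_C))
}

#' @rdname format_profile
#' @param label A profile label such as `"2/5"` or `"5/2"`.
#' @export
parse_profile <- function(label) {
  parts <- strsplit(trimws(label), "/", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) stop("malformed profile label: ", label, call. = FALSE)
  v <- suppressWarnings(as.numeric(parts))
  if (anyNA(v) || any(v <= 0)) stop("malformed profile label: ", label, call. = FALSE)
  embryo <- min(v); endosperm <- max(v)
  list(embryo_C = embryo, endosperm_C = endosperm,
       quotient = endosperm / embryo)
}

#' @export
print.fcss_scenario <- function(x, ...) {
  prof <- expected_c_values(x)
  cat(sprintf("FCSS scenario %s (%s): embryo %gC, endosperm %gC, quotient %.3g\n",
              prof$label, x$mode, prof$embryo_C, prof$endosperm_C,
              prof$quotient))
  invisible(x)
}

#' Enumerate candidate fertilization scenarios for a maternal plant
#'
#' Builds the scenario set against which observed endosperm:embryo quotients
#' are classified. The default set for a mother of ploidy m comprises:
#' sexual double fertilization (reduced egg + one reduced sperm, two reduced
#' polar nuclei + one reduced sperm); apomixis with autonomous endosperm
#' (unreduced parthenogenetic egg, two unreduced polar nuclei, no sperm);
#' and pseudogamous apomixis with one reduced, one unreduced, or two reduced
#' sperms. The extended set adds tri-nucleate central cells (three polar
#' nuclei) and the two-unreduced-sperm combination, and optionally BIII
#' hybrids (unreduced egg fertilized by an unreduced sperm), mirroring the
#' way extended scenario sets are needed only for taxa with unusual
#' profiles.
#'
#' Mechanistically identical scenarios are deduplicated; distinct gamete
#' compositions that share a C-value profile (e.g. the two routes to 2/6)
#' are both kept so that classification can report the tie.
#'
#' @param maternal_ploidy Maternal ploidy m (x units).
#' @param pollen_ploidies Ploidies of plausible pollen donors (default: the
#'   maternal ploidy).
#' @param trinucleate Include tri-nucleate central-cell (k = 3) variants.
#' @param biii Include the BIII hybrid scenario.
#' @param all_sperm_combos Include the two-unreduced-sperm pseudogamy
#'   variant; defaults to on whenever the extended (tri-nucleate or BIII)
#'   set is requested.
#' @param allow_haploid Passed to [scenario_spec()].
#' @return A list of `fcss_scenario` objects, sorted by expected quotient.
#' @export
#' @examples
#' length(enumerate_scenarios(2))                 # default diploid set
#' sapply(enumerate_scenarios(2), function(s) expected_c_values(s)$quotient)
enumerate_scenarios <- function(maternal_ploidy,
                                pollen_ploidies = maternal_ploidy,
                                trinucleate = FALSE,
                                biii = FALSE,
                                all_sperm_combos = trinucleate || biii,
                                allow_haploid = FALSE) {
  m <- maternal_ploidy
  if (length(pollen_ploidies) == 0L) stop("pollen_ploidies must be nonempty")
  k_values <- if (trinucleate) c(2L, 3L) else 2L
  sperm_combos <- list(c(1L, TRUE), c(1L, FALSE), c(2L, TRUE))
  if (all_sperm_combos) sperm_combos <- c(sperm_combos, list(c(2L, FALSE)))

  out <- list()
  add <- function(sc) out[[length(out) + 1L]] <<- sc

  for (p in pollen_ploidies) {
    add(scenario_spec(m, egg_reduced = TRUE, embryo_fertilized = TRUE,
                      polar_nuclei = 2L, polar_reduced = TRUE,
                      endosperm_sperms = 1L, pollen_ploidy = p,
                      sperm_reduced = TRUE, allow_haploid = allow_haploid))
  }
  for (k in k_values) {
    add(scenario_spec(m, egg_reduced = FALSE, embryo_fertilized = FALSE,
                      polar_nuclei = k, polar_reduced = FALSE,
                      endosperm_sperms = 0L, allow_haploid = allow_haploid))
    for (p in pollen_ploidies) {
      for (combo in sperm_combos) {
        add(scenario_spec(m, egg_reduced = FALSE, embryo_fertilized = FALSE,
                          polar_nuclei = k, polar_reduced = FALSE,
                          endosperm_sperms = combo[[1L]], pollen_ploidy = p,
                          sperm_reduced = as.logical(combo[[2L]]),
                          allow_haploid = allow_haploid))
      }
    }
  }
  if (biii) {
    for (p in pollen_ploidies) {
      add(scenario_spec(m, egg_reduced = FALSE, embryo_fertilized = TRUE,
                        polar_nuclei = 2L, polar_reduced = FALSE,
                        endosperm_sperms = 1L, pollen_ploidy = p,
                        sperm_reduced = FALSE, allow_haploid = allow_haploid))
    }
  }

  sig <- vapply(out, function(s) {
    paste(s$maternal_ploidy, s$egg_reduced, s$embryo_fertilized,
          s$polar_nuclei, s$polar_reduced, s$endosperm_sperms,
          s$pollen_ploidy, s$sperm_reduced, sep = "|")
  }, character(1L))
  out <- out[!duplicated(sig)]
  q <- vapply(out, function(s) expected_c_values(s)$quotient, numeric(1L))
  out[order(q)]
}
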
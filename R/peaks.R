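#' Default peak-detection and role-assignment parameters
#'
#' @param min_particles Soft gate on total recorded events; histograms
#'   below it are analysed with a warning (weak herbarium samples are
#'   common), default 5000.
#' @param max_cv Peaks with coefficient of variation above this (%) are
#'   flagged `cv_ok = FALSE`; default 8.
#' @param smooth_width Moving-average width (channels) applied before
#'   maximum finding; default 5.
#' @param prominence_frac A local maximum must reach this fraction of the
#'   tallest smoothed channel to count as a peak; default 0.04.
#' @param window_sigma Half-width of the statistics window in units of the
#'   estimated peak sigma; default 2.5 (captures >= 98\% of a Gaussian
#'   while limiting debris leakage).
#' @param valid_quotient_range Admissible endosperm:embryo quotients;
#'   default c(1.2, 6.0).
#' @param min_endosperm_frac A peak qualifies as a plausible endosperm G1
#'   only when its nuclei count is at least this fraction of the embryo
#'   count; weaker peaks are candidates only for the endopolyploidy
#'   second-peak rule. Default 0.15.
#' @param g2_count_frac Peaks at ~2x the embryo position with fewer than
#'   this fraction of the embryo count are flagged as the embryo G2
#'   replicate; default 0.2.
#' @param second_peak_rule Enable the endopolyploidy rule: when the only
#'   endosperm signal sits at ~2x an expected endosperm position and the
#'   expected G1 position is empty, record the second peak and halve its
#'   mean fluorescence. Default TRUE.
#' @param expected_quotients Expected endosperm:embryo quotients used by
#'   the second-peak rule; default the default diploid scenario set
#'   (1.5, 2, 2.5, 3).
#' @param position_tol Relative tolerance for "near an expected position";
#'   default 0.08.
#' @param standard_window Optional c(lo, hi) fluorescence window holding
#'   the internal-standard peak; the largest peak inside is assigned the
#'   `standard` role and excluded from embryo/endosperm assignment.
#' @return A named list of parameters.
#' @export
peak_params <- function(min_particles = 5000,
                        max_cv = 8,
                        smooth_width = 5L,
                        prominence_frac = 0.04,
                        window_sigma = 2.5,
                        valid_quotient_range = c(1.2, 6.0),
                        min_endosperm_frac = 0.15,
                        g2_count_frac = 0.2,
                        second_peak_rule = TRUE,
                        expected_quotients = c(1.5, 2, 2.5, 3),
                        position_tol = 0.08,
                        standard_window = NULL) {
  list(min_particles = min_particles, max_cv = max_cv,
       smooth_width = as.integer(smooth_width),
       prominence_frac = prominence_frac, window_sigma = window_sigma,
       valid_quotient_range = valid_quotient_range,
       min_endosperm_frac = min_endosperm_frac,
       g2_count_frac = g2_count_frac,
       second_peak_rule = second_peak_rule,
       expected_quotients = expected_quotients,
       position_tol = position_tol,
       standard_window = standard_window)
}

#' Detect G0/G1 peaks in a fluorescence histogram
#'
#' Finds local maxima of the lightly smoothed histogram above a prominence
#' floor, then computes each peak's mean fluorescence, coefficient of
#' variation and nuclei count from the raw counts in a window of
#' +/- `window_sigma` estimated sigmas around the maximum (sigma estimated
#' from the full width at half maximum).
#'
#' @param h An `fcss_histogram`.
#' @param params See [peak_params()].
#' @return A data.frame of class `fcss_peaks`, sorted by position, with
#'   columns `mean_fluorescence`, `cv_percent`, `nuclei_count`,
#'   `channel_max`, `cv_ok`, `role` (all `"unassigned"`).
#' @export
detect_peaks <- function(h, params = peak_params()) {
  stopifnot(inherits(h, "fcss_histogram"))
  total <- sum(h$counts)
  if (total < params$min_particles) {
    warning(sprintf("only %d particles recorded (< %d); peak statistics may be unreliable",
                    total, params$min_particles), call. = FALSE)
  }
  n <- length(h$counts)
  w <- params$smooth_width
  kern <- rep(1 / w, w)
  sm <- as.numeric(stats::filter(h$counts, kern, sides = 2))
  sm[is.na(sm)] <- 0

  floor_h <- params$prominence_frac * max(sm)
  edge <- max(2L, w)
  idx <- which(seq_len(n) > edge & seq_len(n) <= n - edge &
                 sm > c(-Inf, sm[-n]) & sm >= c(sm[-1L], Inf) & sm >= floor_h)
  if (length(idx) == 0L) {
    stop(structure(class = c("fcss_no_peaks", "error", "condition"),
                   list(message = paste0("no peaks detected in sample '",
                                         h$sample_id, "'"),
                        call = NULL)))
  }
  # collapse runs of adjacent candidate maxima (plateaus) to their center
  grp <- cumsum(c(1L, diff(idx) > 2L))
  idx <- vapply(split(idx, grp), function(ii) ii[which.max(sm[ii])][1L],
                integer(1L))

  stats_at <- function(i) {
    half <- sm[i] / 2
    l <- i; while (l > 1L && sm[l] > half) l <- l - 1L
    r <- i; while (r < n && sm[r] > half) r <- r + 1L
    fwhm <- h$channels[r] - h$channels[l]
    sigma <- max(fwhm / 2.355, diff(range(h$channels)) / n)
    lo <- h$channels[i] - params$window_sigma * sigma
    hi <- h$channels[i] + params$window_sigma * sigma
    sel <- h$channels >= lo & h$channels <= hi
    cnt <- h$counts[sel]
    ch <- h$channels[sel]
    m <- sum(ch * cnt) / sum(cnt)
    sdev <- sqrt(sum(cnt * (ch - m)^2) / sum(cnt))
    c(mean = m, cv = 100 * sdev / m, count = sum(cnt))
  }
  st <- t(vapply(idx, stats_at, numeric(3L)))
  out <- data.frame(mean_fluorescence = st[, "mean"],
                    cv_percent = st[, "cv"],
                    nuclei_count = st[, "count"],
                    channel_max = h$channels[idx],
                    cv_ok = st[, "cv"] <= params$max_cv,
                    role = "unassigned",
                    stringsAsFactors = FALSE)
  out <- out[out$nuclei_count >= 1, , drop = FALSE]
  out <- out[order(out$mean_fluorescence), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fcss_peaks", "data.frame")
  out
}

#' Assign embryo / endosperm / standard roles and derive the seed measurement
#'
#' The embryo is the dominant peak (largest nuclei count outside the
#' internal-standard window; ties broken toward the lower position, which
#' is logged). The endosperm G1 is the nearest peak above the embryo whose
#' quotient lies in the admissible range and whose count is a plausible
#' fraction of the embryo count; weak peaks at ~2x the embryo are flagged
#' as the embryo G2 replicate. When strong endopolyploidy suppresses the
#' endosperm G1 peak, the endosperm second (replicate) peak is recorded
#' instead and its mean fluorescence divided by two
#' (`used_second_peak = TRUE`). With no endosperm signal at all a
#' no-endosperm measurement is returned.
#'
#' @param peaks An `fcss_peaks` data.frame from [detect_peaks()].
#' @param h The originating `fcss_histogram` (metadata: internal standard).
#' @param params See [peak_params()].
#' @return A list of class `fcss_seed` with elements `embryo` (one-row
#'   data.frame), `endosperm_effective_mean`, `endosperm_counts`,
#'   `used_second_peak`, `quotient`, `endosperm_percent`,
#'   `embryo_relative_gs`, `endosperm_relative_gs` (pg, when an internal
#'   standard was identified), `no_endosperm`, annotated `peaks`, and
#'   `notes` (log of tie-breaks and rule applications).
#' @export
assign_roles <- function(peaks, h, params = peak_params()) {
  stopifnot(inherits(peaks, "data.frame"), nrow(peaks) >= 1L)
  notes <- character(0)
  pk <- as.data.frame(peaks)
  pk$role <- "unassigned"

  std_i <- integer(0)
  if (!is.null(params$standard_window)) {
    inw <- which(pk$mean_fluorescence >= params$standard_window[[1L]] &
                   pk$mean_fluorescence <= params$standard_window[[2L]])
    if (length(inw)) {
      std_i <- inw[which.max(pk$nuclei_count[inw])]
      pk$role[std_i] <- "standard"
    }
  }
  cand <- setdiff(seq_len(nrow(pk)), std_i)
  if (length(cand) == 0L) stop("all peaks fall in the standard window")

  cmax <- max(pk$nuclei_count[cand])
  emb_cand <- cand[pk$nuclei_count[cand] >= cmax * (1 - 1e-9)]
  if (length(emb_cand) > 1L) {
    notes <- c(notes, sprintf(
      "ambiguous embryo (%d equal-count peaks); tie broken toward lower position",
      length(emb_cand)))
  }
  emb_i <- emb_cand[which.min(pk$mean_fluorescence[emb_cand])]
  pk$role[emb_i] <- "embryo_G1"
  emb_mean <- pk$mean_fluorescence[emb_i]
  emb_count <- pk$nuclei_count[emb_i]

  rest <- setdiff(cand, emb_i)
  q <- pk$mean_fluorescence[rest] / emb_mean
  in_range <- q >= params$valid_quotient_range[[1L]] &
    q <= params$valid_quotient_range[[2L]]
  frac <- pk$nuclei_count[rest] / emb_count
  is_g2 <- abs(q / 2 - 1) <= params$position_tol / 2 &
    frac < params$g2_count_frac
  pk$role[rest[is_g2 & frac < params$min_endosperm_frac]] <- "embryo_G2"

  strong <- rest[in_range & !is_g2 & frac >= params$min_endosperm_frac]
  weak <- rest[in_range & frac < params$min_endosperm_frac]

  endo_mean <- endo_count <- NA_real_
  used_second <- FALSE
  no_endosperm <- FALSE
  if (length(strong)) {
    e_i <- strong[which.min(pk$mean_fluorescence[strong])]
    pk$role[e_i] <- "endosperm_G1"
    endo_mean <- pk$mean_fluorescence[e_i]
    endo_count <- pk$nuclei_count[e_i]
  } else if (params$second_peak_rule && length(weak)) {
    qualifies <- vapply(weak, function(i) {
      qq <- pk$mean_fluorescence[i] / emb_mean
      tgt <- params$expected_quotients
      near2x <- abs(qq / (2 * tgt) - 1) <= params$position_tol
      if (!any(near2x)) return(FALSE)
      g1_pos <- tgt[near2x] * emb_mean
      any(vapply(g1_pos, function(gp) {
        !any(abs(pk$mean_fluorescence / gp - 1) <= params$position_tol)
      }, logical(1L)))
    }, logical(1L))
    if (any(qualifies)) {
      wq <- weak[qualifies]
      e_i <- wq[which.min(pk$mean_fluorescence[wq])]
      pk$role[e_i] <- "endosperm_second"
      endo_mean <- pk$mean_fluorescence[e_i] / 2
      endo_count <- pk$nuclei_count[e_i]
      used_second <- TRUE
      notes <- c(notes, sprintf(
        "endopolyploidy second-peak rule applied: peak at %.1f halved to %.1f",
        pk$mean_fluorescence[e_i], endo_mean))
    } else {
      no_endosperm <- TRUE
    }
  } else {
    no_endosperm <- TRUE
  }
  if (no_endosperm) notes <- c(notes, "no endosperm signal detected")

  quotient <- if (no_endosperm) NA_real_ else endo_mean / emb_mean
  endo_pct <- if (no_endosperm) NA_real_ else
    endosperm_percentage(emb_count, endo_count)

  emb_gs <- endo_gs <- NA_real_
  if (length(std_i) && !is.na(h$standard_2C_pg)) {
    std_mean <- pk$mean_fluorescence[std_i]
    emb_gs <- relative_genome_size(emb_mean, std_mean, h$standard_2C_pg)
    if (!no_endosperm) {
      endo_gs <- relative_genome_size(endo_mean, std_mean, h$standard_2C_pg)
    }
  }

  structure(list(sample_id = h$sample_id, species = h$species,
                 embryo = pk[emb_i, , drop = FALSE],
                 endosperm_effective_mean = endo_mean,
                 endosperm_counts = endo_count,
                 used_second_peak = used_second,
                 quotient = quotient,
                 endosperm_percent = endo_pct,
                 embryo_relative_gs = emb_gs,
                 endosperm_relative_gs = endo_gs,
                 no_endosperm = no_endosperm,
                 peaks = pk, notes = notes),
            class = "fcss_seed")
}

#' @export
print.fcss_seed <- function(x, ...) {
  if (x$no_endosperm) {
    cat(sprintf("FCSS seed '%s': embryo at %.1f, no endosperm signal\n",
                x$sample_id, x$embryo$mean_fluorescence))
  } else {
    cat(sprintf("FCSS seed '%s': embryo %.1f, endosperm %.1f%s, quotient %.3f, endosperm %.1f%% of nuclei\n",
                x$sample_id, x$embryo$mean_fluorescence,
                x$endosperm_effective_mean,
                if (x$used_second_peak) " (second peak / 2)" else "",
                x$quotient, x$endosperm_percent))
  }
  invisible(x)
}

#' Percentage of endosperm nuclei in a seed
#'
#' The relative amount of endosperm is the count of nuclei under the
#' endosperm peak as a share of the nuclei under both G1 peaks; it is
#' scale-invariant in the counts.
#'
#' @param embryo_count,endosperm_count Nuclei counts (>= 0, not both 0).
#' @return Percentage in [0, 100].
#' @export
#' @examples
#' endosperm_percentage(500, 500)   # 50
#' endosperm_percentage(1000, 500)  # 33.33
endosperm_percentage <- function(embryo_count, endosperm_count) {
  stopifnot(embryo_count >= 0, endosperm_count >= 0)
  if (embryo_count + endosperm_count == 0) {
    stop("both nuclei counts are zero; percentage undefined", call. = FALSE)
  }
  100 * endosperm_count / (embryo_count + endosperm_count)
}

#' Genome size relative to a co-processed internal standard
#'
#' Converts a peak's mean fluorescence to picograms via an internal
#' standard of known 2C DNA content (e.g. Pisum sativum 'Ctirad'
#' 2C = 9.09 pg; Bellis perennis 2C = 3.38 pg), assuming fluorescence is
#' linear in DNA amount.
#'
#' @param peak_mean,standard_mean Mean fluorescences (> 0).
#' @param standard_2C_pg The standard's 2C DNA amount in pg (> 0).
#' @return Genome size in pg.
#' @export
relative_genome_size <- function(peak_mean, standard_mean, standard_2C_pg) {
  if (missing(standard_2C_pg) || is.na(standard_2C_pg)) {
    stop("no internal standard metadata; use quotient-only mode ",
         "(classify_quotient) for samples without a standard", call. = FALSE)
  }
  stopifnot(peak_mean > 0, standard_mean > 0, standard_2C_pg > 0)
  peak_mean / standard_mean * standard_2C_pg
}
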
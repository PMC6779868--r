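#' Redundancy-analysis pseudo-F for a two-group comparison
#'
#' Constrained ordination of a multivariate trait matrix on a single
#' binary predictor reduces to the projection of the centered, scaled
#' trait matrix onto the centered group indicator. With q = 1 constrained
#' axis,
#' \deqn{pseudo\mbox{-}F = \frac{SS_{explained} / 1}{SS_{residual} / (n - 2)}}
#' where the sums of squares are summed over all trait columns. On a
#' single column this is exactly the classical one-way two-group ANOVA F.
#'
#' Columns are centered and scaled to unit variance first (traits come in
#' mixed units); constant columns are dropped with a warning.
#'
#' @param Y Numeric matrix or data.frame of traits (rows = species).
#' @param x Binary group membership (two levels; numeric 0/1, logical or
#'   factor/character with two levels).
#' @return A list with `pseudo_F`, `variance_explained`
#'   (SS_explained / SS_total), `ss_explained`, `ss_total`, `n`, `p`
#'   (columns used).
#' @export
#' @examples
#' y <- c(rnorm(10), rnorm(10, 1))
#' g <- rep(0:1, each = 10)
#' all.equal(rda_pseudo_F(y, g)$pseudo_F,
#'           summary(aov(y ~ factor(g)))[[1]]$`F value`[1])
rda_pseudo_F <- function(Y, x) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  x <- as_binary01(x)
  n <- nrow(Y)
  stopifnot(n >= 4, length(x) == n)
  if (length(unique(x)) < 2L) {
    stop("both groups must be present in x", call. = FALSE)
  }
  sds <- apply(Y, 2L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d constant trait column(s)", sum(sds == 0)),
            call. = FALSE)
    Y <- Y[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
    if (ncol(Y) == 0L) stop("no non-constant trait columns", call. = FALSE)
  }
  Ys <- scale(Y, center = TRUE, scale = sds)
  xc <- x - mean(x)
  ss_tot <- sum(Ys^2)
  # fitted values of Ys ~ xc: SS_explained = ||xc' Ys||^2 / (xc' xc)
  ss_exp <- sum(crossprod(xc, Ys)^2) / sum(xc^2)
  ss_res <- ss_tot - ss_exp
  list(pseudo_F = (ss_exp / 1) / (ss_res / (n - 2)),
       variance_explained = ss_exp / ss_tot,
       ss_explained = ss_exp, ss_total = ss_tot,
       n = n, p = ncol(Ys))
}

as_binary01 <- function(x) {
  if (is.logical(x)) return(as.numeric(x))
  if (is.numeric(x)) {
    u <- sort(unique(x))
    if (length(u) > 2L) stop("x must have two levels", call. = FALSE)
    return(as.numeric(x == u[length(u)]))
  }
  f <- factor(x)
  if (nlevels(f) > 2L) stop("x must have two levels", call. = FALSE)
  as.numeric(f == levels(f)[nlevels(f)])
}

#' Monte Carlo permutation test of the RDA pseudo-F
#'
#' Permutes the rows of the group indicator and recomputes pseudo-F;
#' the p-value is (1 + number of permuted F >= observed F) / (1 + n_perm),
#' so the smallest achievable p is 1 / (n_perm + 1). Reproducible for a
#' fixed seed.
#'
#' @param Y,x As in [rda_pseudo_F()].
#' @param n_perm Number of permutations (>= 99); screens typically use
#'   9999.
#' @param rng_seed Integer seed.
#' @return A list of class `fcss_rda` with `pseudo_F`, `p_value`,
#'   `variance_explained`, `n_permutations`, `rng_seed`, `n`, `p`.
#' @export
permutation_test <- function(Y, x, n_perm = 9999L, rng_seed = 1L) {
  stopifnot(n_perm >= 99L)
  obs <- rda_pseudo_F(Y, x)
  # precompute the scaled response once; permute the centered indicator
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  sds <- apply(Y, 2L, stats::sd)
  Ys <- scale(Y[, sds > 0, drop = FALSE], center = TRUE,
              scale = sds[sds > 0])
  xb <- as_binary01(x)
  n <- nrow(Ys)
  ss_tot <- sum(Ys^2)
  f_of <- function(xp) {
    xc <- xp - mean(xp)
    ss_exp <- sum(crossprod(xc, Ys)^2) / sum(xc^2)
    (ss_exp) / ((ss_tot - ss_exp) / (n - 2))
  }
  f_perm <- with_seed(rng_seed, {
    vapply(seq_len(n_perm), function(i) f_of(xb[sample.int(n)]), numeric(1L))
  })
  p <- (1 + sum(f_perm >= obs$pseudo_F - 1e-12)) / (1 + n_perm)
  structure(list(pseudo_F = obs$pseudo_F, p_value = p,
                 variance_explained = obs$variance_explained,
                 n_permutations = as.integer(n_perm),
                 rng_seed = as.integer(rng_seed),
                 n = obs$n, p = obs$p),
            class = "fcss_rda")
}

#' @export
print.fcss_rda <- function(x, ...) {
  cat(sprintf("RDA: pseudo-F = %.3g, P = %.4g (%d permutations), %.1f%% variance explained\n",
              x$pseudo_F, x$p_value, x$n_permutations,
              100 * x$variance_explained))
  invisible(x)
}

#' Per-trait univariate summary of apomicts vs sexuals
#'
#' For each trait: group means (proportions for binary traits) and a
#' two-sided test of the group difference — a permutation test on the
#' mean difference for continuous traits, Fisher's exact test for binary
#' traits — with conventional significance stars (ns, * P < 0.05,
#' ** P < 0.01, *** P < 0.001). Traits with fewer than two observations
#' in either group are marked not testable.
#'
#' @param traits Data.frame with a `mode_label` column (two levels, the
#'   alphabetically first is reported first) and trait columns; e.g. the
#'   output of [simulate_trait_table()].
#' @param binary Character vector of binary trait column names; defaults
#'   to columns containing only 0/1.
#' @param n_perm Permutations for the continuous-trait test, default 999.
#' @param rng_seed Integer seed.
#' @param holm Apply Holm adjustment across traits before assigning stars
#'   (off by default, as trait tables conventionally report unadjusted
#'   stars).
#' @return A data.frame with one row per trait: `trait`, `type`,
#'   `mean_apomict`, `mean_non_apomict`, `p_value`, `stars`.
#' @export
table1_summary <- function(traits, binary = NULL, n_perm = 999L,
                           rng_seed = 1L, holm = FALSE) {
  stopifnot("mode_label" %in% names(traits))
  g <- factor(traits$mode_label)
  stopifnot(nlevels(g) == 2L)
  trait_cols <- setdiff(names(traits), c("species", "mode_label"))
  if (is.null(binary)) {
    binary <- trait_cols[vapply(trait_cols, function(cn) {
      v <- traits[[cn]]
      is.numeric(v) && all(v %in% c(0, 1))
    }, logical(1L))]
  }
  g1 <- levels(g)[1L]; g2 <- levels(g)[2L]

  seeds <- with_seed(rng_seed,
                     sample.int(.Machine$integer.max - 1L, length(trait_cols)))
  rows <- lapply(seq_along(trait_cols), function(i) {
    cn <- trait_cols[[i]]
    v <- traits[[cn]]
    m1 <- mean(v[g == g1]); m2 <- mean(v[g == g2])
    testable <- min(table(g[!is.na(v)])) >= 2L
    p <- NA_real_
    if (testable) {
      if (cn %in% binary) {
        p <- stats::fisher.test(table(v, g))$p.value
      } else {
        d_obs <- abs(m1 - m2)
        gl <- g
        d_perm <- with_seed(seeds[[i]], {
          vapply(seq_len(n_perm), function(k) {
            gp <- gl[sample.int(length(gl))]
            abs(mean(v[gp == g1]) - mean(v[gp == g2]))
          }, numeric(1L))
        })
        p <- (1 + sum(d_perm >= d_obs - 1e-12)) / (1 + n_perm)
      }
    }
    data.frame(trait = cn,
               type = if (cn %in% binary) "binary" else "continuous",
               mean_1 = m1, mean_2 = m2, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "mean_1"] <- paste0("mean_", g1)
  names(out)[names(out) == "mean_2"] <- paste0("mean_", g2)
  p_for_stars <- if (holm) stats::p.adjust(out$p_value, "holm") else out$p_value
  out$stars <- ifelse(is.na(p_for_stars), "not_testable",
               ifelse(p_for_stars < 0.001, "***",
               ifelse(p_for_stars < 0.01, "**",
               ifelse(p_for_stars < 0.05, "*", "ns"))))
  out
}
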
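#' Mann-Whitney U test (normal approximation with tie correction)
#'
#' Two-sided test for a location difference between two samples, reported as
#' the standardized statistic \eqn{z = (U - n_1 n_2 / 2) / \sigma_U} with
#' tie-corrected \eqn{\sigma_U} and no continuity correction — the
#' convention of the desktop statistics packages traditionally used for
#' this kind of comparative table. The absolute z is reported as the test
#' statistic, with its sign alongside.
#'
#' @param x,y numeric samples.
#' @param continuity apply the 0.5 continuity correction (default FALSE).
#' @return list of class \code{annna_test}: \code{statistic} (|z|),
#'   \code{sign}, \code{U} (for the first sample), \code{p}, \code{kind},
#'   \code{n1}, \code{n2}.
#' @export
mann_whitney <- function(x, y, continuity = FALSE) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term)
  if (sigma2 <= 0) {       # every value tied across both samples
    z <- 0
  } else {
    num <- U - mu
    if (continuity) num <- sign(num) * max(0, abs(num) - 0.5)
    z <- num / sqrt(sigma2)
  }
  p <- if (z == 0) 1 else 2 * stats::pnorm(-abs(z))
  structure(list(statistic = abs(z), sign = sign(z), U = U, p = p,
                 kind = "mwu_z", n1 = n1, n2 = n2),
            class = "annna_test")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Compares the shapes of two univariate distributions:
#' \eqn{D = \sup |ECDF_x - ECDF_y|}, with the asymptotic two-sided p-value.
#'
#' @param x,y numeric samples.
#' @return list of class \code{annna_test} with \code{statistic} (D),
#'   \code{p}, \code{kind = "ks_d"}, \code{n1}, \code{n2}.
#' @export
ks_compare <- function(x, y) {
  res <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  structure(list(statistic = unname(res$statistic), sign = NA,
                 p = res$p.value, kind = "ks_d",
                 n1 = length(x), n2 = length(y)),
            class = "annna_test")
}

#' @export
print.annna_test <- function(x, ...) {
  ns <- if (!is.null(x$n1)) c(x$n1, x$n2) else x$n
  cat(x$kind, ": statistic =", format(x$statistic, digits = 4),
      " p =", format(x$p, digits = 4),
      " (n =", paste(ns, collapse = ", "), ")\n")
  invisible(x)
}

#' Ordinary least-squares regression of a trait on relative size
#'
#' @param x covariate (e.g. relative skull size, percent).
#' @param y response (a network parameter or principal coordinate).
#' @return list: \code{slope}, \code{intercept}, \code{r2},
#'   \code{p_slope} (two-sided t-test on the slope), \code{n}, and the
#'   underlying \code{lm} fit.
#' @export
ols_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0) stop("covariate has zero variance")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = s$r.squared,
       p_slope = s$coefficients[2, 4],
       n = length(x),
       fit = fit)
}

#' ANCOVA test for equality of two regression slopes
#'
#' One-way ANCOVA F-test of the group-by-covariate interaction: the model
#' with separate slopes against the common-slope model. Used to compare the
#' juvenile and adult allometric regressions of each parameter.
#'
#' @param x1,y1 covariate and response for group 1.
#' @param x2,y2 covariate and response for group 2.
#' @return list: \code{F}, \code{p}, \code{df1} (= 1), \code{df2}
#'   (= n1 + n2 - 4).
#' @export
ancova_slopes <- function(x1, y1, x2, y2) {
  stopifnot(length(x1) == length(y1), length(x2) == length(y2),
            length(x1) >= 3, length(x2) >= 3)
  g <- factor(rep(c("g1", "g2"), c(length(x1), length(x2))))
  x <- c(x1, x2); y <- c(y1, y2)
  full <- stats::lm(y ~ x * g)
  reduced <- stats::lm(y ~ x + g)
  a <- stats::anova(reduced, full)
  df2 <- length(x) - 4
  if (df2 <= 0) stop("no residual degrees of freedom")
  list(F = a$F[2], p = a$`Pr(>F)`[2], df1 = 1, df2 = df2)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance (distance-based
#' pseudo-F), permuting raw group labels, with p-value
#' \eqn{(\#\{F^{perm} \ge F\} + 1) / (nperm + 1)}. Pairwise two-group tests
#' are Bonferroni-corrected by multiplying p by the number of comparisons
#' (capped at 1). The sum-of-squares decomposition is delegated to
#' \code{vegan}'s \code{adonis2}.
#'
#' @param d distance matrix or \code{dist} object.
#' @param groups group labels, one per row of \code{d}.
#' @param nperm number of permutations (default 10000).
#' @param seed optional RNG seed for the permutations.
#' @param pairwise also run all two-group comparisons?
#' @return list of class \code{annna_test}: \code{statistic} (pseudo-F),
#'   \code{p}, \code{kind = "permanova_F"}, group sizes, and a
#'   \code{pairwise} data frame with raw and Bonferroni p-values.
#' @export
permanova <- function(d, groups, nperm = 10000, seed = NULL,
                      pairwise = TRUE) {
  if (!inherits(d, "dist")) d <- stats::as.dist(as.matrix(d))
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2))
    stop("each group needs n >= 2 for the overall test")
  if (!is.null(seed)) set.seed(seed)
  one_test <- function(dd, gg) {
    df <- data.frame(g = gg)
    fit <- vegan::adonis2(dd ~ g, data = df, permutations = nperm)
    list(F = fit$F[1], p = fit$`Pr(>F)`[1])
  }
  overall <- one_test(d, groups)
  pw <- NULL
  if (pairwise && nlevels(groups) > 2) {
    combos <- utils::combn(levels(groups), 2)
    m <- as.matrix(d)
    rows <- list()
    for (i in seq_len(ncol(combos))) {
      a <- combos[1, i]; b <- combos[2, i]
      sel <- groups %in% c(a, b)
      if (sum(groups == a) < 2 || sum(groups == b) < 2) {
        warning("pairwise test ", a, " vs ", b,
                " skipped: a group has n < 2")
        next
      }
      sub <- one_test(stats::as.dist(m[sel, sel]), droplevels(groups[sel]))
      rows[[length(rows) + 1]] <-
        data.frame(group1 = a, group2 = b, F = sub$F, p_raw = sub$p)
    }
    if (length(rows)) {
      pw <- do.call(rbind, rows)
      pw$p_bonferroni <- pmin(1, pw$p_raw * nrow(pw))
    }
  }
  structure(list(statistic = overall$F, p = overall$p,
                 kind = "permanova_F",
                 n = as.integer(table(groups)),
                 nperm = nperm, pairwise = pw),
            class = "annna_test")
}

#' Relative skull size covariates
#'
#' For each juvenile, relative size is the percentage of its own species'
#' adult skull box volume; for each adult, the percentage of the largest
#' adult skull box volume in the sample (the biggest bird sampled sets
#' 100\%).
#'
#' @param meta metadata data frame from \code{\link{read_specimen_meta}}
#'   with a \code{box_volume} column and \code{stage}/\code{taxon} columns.
#' @return \code{meta} with an added \code{relative_size} column (percent).
#' @export
relative_skull_size <- function(meta) {
  if (is.null(meta$box_volume))
    stop("metadata needs box dimensions (box_volume)")
  meta$relative_size <- NA_real_
  adults <- meta[meta$stage == "adult", ]
  max_adult <- max(adults$box_volume, na.rm = TRUE)
  for (i in seq_len(nrow(meta))) {
    if (meta$stage[i] == "adult") {
      meta$relative_size[i] <- 100 * meta$box_volume[i] / max_adult
    } else {
      ad <- adults$box_volume[adults$taxon == meta$taxon[i]]
      if (length(ad) == 1 && !is.na(ad))
        meta$relative_size[i] <- 100 * meta$box_volume[i] / ad
    }
  }
  meta
}

#' Group-comparison table of network parameters
#'
#' For every parameter column and every pair of groups, runs the
#' Mann-Whitney and Kolmogorov-Smirnov tests — the layout of the classic
#' group-difference table.
#'
#' @param tab parameter (or coordinate) table, rows = specimens.
#' @param groups group label per row.
#' @return long data frame: variable, group pair, z, p_z, D, p_D.
#' @export
compare_groups <- function(tab, groups) {
  groups <- factor(groups)
  stopifnot(nrow(tab) == length(groups))
  combos <- utils::combn(levels(groups), 2)
  out <- list()
  for (v in colnames(tab)) {
    for (i in seq_len(ncol(combos))) {
      a <- combos[1, i]; b <- combos[2, i]
      x <- tab[groups == a, v]; y <- tab[groups == b, v]
      mw <- mann_whitney(x, y)
      ks <- ks_compare(x, y)
      out[[length(out) + 1]] <- data.frame(
        variable = v, group1 = a, group2 = b,
        z = mw$statistic, z_sign = mw$sign, p_z = mw$p,
        D = ks$statistic, p_D = ks$p)
    }
  }
  do.call(rbind, out)
}

#' Allometric regression table with slope ANCOVA
#'
#' For every column, regresses the trait on relative size separately in two
#' stage groups and tests the equality of the two slopes with ANCOVA — the
#' layout of the classic ontogeny-vs-allometry table.
#'
#' @param tab trait table, rows = specimens.
#' @param size relative size covariate per row.
#' @param stage factor with levels including \code{"juvenile"} and
#'   \code{"adult"}.
#' @return data frame: variable, juvenile slope/R2/p, adult slope/R2/p,
#'   ANCOVA F and p.
#' @export
regression_table <- function(tab, size, stage) {
  stopifnot(nrow(tab) == length(size), length(size) == length(stage))
  j <- stage == "juvenile"; a <- stage == "adult"
  out <- list()
  for (v in colnames(tab)) {
    fj <- ols_fit(size[j], tab[j, v])
    fa <- ols_fit(size[a], tab[a, v])
    an <- ancova_slopes(size[j], tab[j, v], size[a], tab[a, v])
    out[[length(out) + 1]] <- data.frame(
      variable = v,
      slope_juv = fj$slope, r2_juv = fj$r2, p_juv = fj$p_slope,
      slope_adult = fa$slope, r2_adult = fa$r2, p_adult = fa$p_slope,
      ancova_F = an$F, ancova_p = an$p)
  }
  do.call(rbind, out)
}
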
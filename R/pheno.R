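#' Growing degree days from a daily temperature series
#'
#' Daily GDD is `max(0, (tmax + tmin)/2 - base)` (negative days truncate
#' to zero, never subtract); `gdd()` returns the cumulative sum over the
#' series. Additive over date ranges.
#'
#' @param series data.frame with columns `tmax`, `tmin` (and optionally
#'   `day`), `tmax >= tmin` daily.
#' @param base base temperature, deg C (the forage-phenology convention
#'   is 5).
#' @return numeric vector of cumulative GDD, one value per day.
#' @export
gdd <- function(series, base = 5) {
  stopifnot(all(c("tmax", "tmin") %in% names(series)))
  if (any(series$tmax < series$tmin)) stop("tmax < tmin in series")
  cumsum(pmax(0, (series$tmax + series$tmin) / 2 - base))
}

#' Thermal time to flowering
#'
#' GDD accumulated from the start of the series (row 1, the default
#' season start) to the flowering day, inclusive.
#'
#' @inheritParams gdd
#' @param flower_day row index (or `day` value if the series has a `day`
#'   column) of first flower.
#' @return scalar GDD.
#' @export
days_to_flower_gdd <- function(series, flower_day, base = 5) {
  idx <- if ("day" %in% names(series)) match(flower_day, series$day) else flower_day
  if (is.na(idx) || idx < 1 || idx > nrow(series)) {
    stop("flower_day outside the temperature series")
  }
  g <- gdd(series, base = base)
  g[idx]
}

#' One-way ANOVA with Tukey HSD mean separation letters
#'
#' Fixed-effects one-way ANOVA followed by all pairwise comparisons on
#' the studentized-range distribution with the Tukey-Kramer adjustment
#' for unbalanced group sizes, summarized as a compact letter display
#' (insert-and-absorb): groups sharing any letter are not significantly
#' different at `alpha`, significantly different groups never share a
#' letter, and no letter set is redundant. `SEM = sqrt(MSE / n_h)` with
#' `n_h` the harmonic mean group size.
#'
#' @param values numeric response.
#' @param groups group labels (coerced to factor), >= 2 groups with >= 2
#'   observations each.
#' @param alpha family-wise significance level.
#' @return object of class `tukey_table`: data.frame `table` (`group`,
#'   `n`, `mean`, `letters`, ordered by decreasing mean), plus `p_value`
#'   (group factor F-test), `sem`, `alpha`, `mse`, `pairwise` (matrix of
#'   Tukey-adjusted p-values).
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) >= 2, all(table(groups) >= 2))
  fit <- aov(values ~ groups)
  p_f <- summary(fit)[[1]][["Pr(>F)"]][1]
  mse <- summary(fit)[[1]][["Mean Sq"]][2]
  df_err <- fit$df.residual
  ng <- nlevels(groups)
  n_g <- as.numeric(table(groups))
  means <- tapply(values, groups, mean)
  n_h <- ng / sum(1 / n_g)
  sem <- sqrt(mse / n_h)

  # Tukey-Kramer pairwise adjusted p-values
  pw <- matrix(NA_real_, ng, ng, dimnames = list(levels(groups), levels(groups)))
  for (i in seq_len(ng - 1)) {
    for (j in (i + 1):ng) {
      if (mse <= 0) {
        p <- if (means[i] == means[j]) 1 else 0
      } else {
        se <- sqrt(mse / 2 * (1 / n_g[i] + 1 / n_g[j]))
        p <- ptukey(abs(means[i] - means[j]) / se, nmeans = ng, df = df_err,
                    lower.tail = FALSE)
      }
      pw[i, j] <- pw[j, i] <- p
    }
  }
  sig <- pw < alpha

  letters <- compact_letter_display(sig, order(means, decreasing = TRUE))
  tab <- data.frame(group = levels(groups), n = n_g, mean = as.numeric(means),
                    letters = letters, row.names = NULL)
  tab <- tab[order(-tab$mean), ]
  rownames(tab) <- NULL
  structure(list(table = tab, p_value = p_f, sem = sem, alpha = alpha,
                 mse = mse, pairwise = pw),
            class = "tukey_table")
}

#' @export
print.tukey_table <- function(x, ...) {
  cat(sprintf("tukey_table (alpha = %g, group p = %.3g, SEM = %.3g)\n",
              x$alpha, x$p_value, x$sem))
  print(x$table, ...)
  invisible(x)
}

# Insert-and-absorb compact letter display. `sig` is a symmetric logical
# matrix (TRUE = significantly different); `pref_order` orders letter
# assignment so 'a' goes with the largest mean.
compact_letter_display <- function(sig, pref_order = seq_len(nrow(sig))) {
  ng <- nrow(sig)
  sets <- list(seq_len(ng))
  for (i in seq_len(ng - 1)) {
    for (j in (i + 1):ng) {
      if (!isTRUE(sig[i, j])) next
      new_sets <- list()
      for (s in sets) {
        if (i %in% s && j %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      # absorb: drop sets that are subsets of another
      keep <- rep(TRUE, length(new_sets))
      for (a in seq_along(new_sets)) {
        for (b in seq_along(new_sets)) {
          if (a != b && keep[a] &&
              all(new_sets[[a]] %in% new_sets[[b]]) &&
              (length(new_sets[[a]]) < length(new_sets[[b]]) || a > b)) {
            keep[a] <- FALSE
          }
        }
      }
      sets <- unique(new_sets[keep])
    }
  }
  # order letters by the first (preferred) member they contain
  first_member <- vapply(sets, function(s) min(match(s, pref_order)), numeric(1))
  sets <- sets[order(first_member)]
  out <- character(ng)
  for (si in seq_along(sets)) {
    for (g in sets[[si]]) {
      out[g] <- paste0(out[g], letters[si])
    }
  }
  out
}

#' Regress a phenotype on admixture membership probability
#'
#' Ordinary least squares of the trait on the membership proportion
#' (e.g. sativa parentage), the standard summary of how strongly a trait
#' tracks the ancestry gradient.
#'
#' @param trait numeric trait values.
#' @param membership membership probabilities in `[0, 1]`, same length.
#' @return list of class `membership_regression`: `slope`, `intercept`,
#'   `r_squared`, `p_value` (slope t-test), `se` (slope SE), `n`.
#'   Zero-variance membership gives `NA` results with a warning.
#' @export
membership_regression <- function(trait, membership) {
  ok <- !is.na(trait) & !is.na(membership)
  trait <- trait[ok]; membership <- membership[ok]
  n <- length(trait)
  if (n < 3) stop("need at least 3 complete observations")
  if (sd(membership) == 0) {
    warning("membership has zero variance; regression undefined")
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          r_squared = NA_real_, p_value = NA_real_,
                          se = NA_real_, n = n),
                     class = "membership_regression"))
  }
  if (sd(trait) == 0) {
    # constant trait: flat fit with no explained variance
    return(structure(list(slope = 0, intercept = trait[1], r_squared = 0,
                          p_value = 1, se = 0, n = n),
                     class = "membership_regression"))
  }
  fit <- lm(trait ~ membership)
  sm <- summary(fit)
  structure(list(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2, 4],
    se = sm$coefficients[2, 2], n = n
  ), class = "membership_regression")
}

#' @export
print.membership_regression <- function(x, ...) {
  cat(sprintf(
    "membership_regression: slope = %.4g (SE %.3g), R2 = %.3f, p = %.3g, n = %d\n",
    x$slope, x$se, x$r_squared, x$p_value, x$n))
  invisible(x)
}
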
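#' Arcsine square-root transform of a proportion
#'
#' `asin(sqrt(p))` in radians, the variance-stabilizing transform applied
#' to per-tube mortality proportions before ANOVA.
#'
#' @param p proportion(s) in [0, 1].
#' @return transformed value(s) in [0, pi/2].
#' @export
arcsineTransform <- function(p) {
  p <- as.numeric(p)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("proportions must lie in [0, 1]")
  asin(sqrt(p))
}

.check_records <- function(records) {
  need <- c("group", "tube", "exposed", "dead")
  if (!all(need %in% names(records)))
    stop("'records' must have columns: ", paste(need, collapse = ", "))
  if (any(records$exposed < 1)) stop("'exposed' must be >= 1 in every tube")
  if (any(records$dead < 0 | records$dead > records$exposed))
    stop("'dead' must satisfy 0 <= dead <= exposed")
  if ("insecticide" %in% names(records) &&
      length(unique(records$insecticide)) > 1L)
    stop("analyse one insecticide at a time (split the records first)")
  records
}

#' Mortality ANOVA with Tukey post hoc for one insecticide
#'
#' Per-tube mortality (dead/exposed) is arcsine square-root transformed and
#' compared across treatment groups by one-way ANOVA with the replicate
#' tube as the experimental unit; all-pairs Tukey HSD adjusted p-values use
#' the studentized-range distribution. Assumption checks (Bartlett for
#' variance homogeneity across groups, Shapiro-Wilk for normality of the
#' pooled ANOVA residuals) are attached. The fully degenerate case of
#' identical transformed values in every tube reports F = 0 and all p = 1.
#'
#' @param records data.frame with columns `group`, `tube`, `exposed`,
#'   `dead` (and optionally a single-valued `insecticide`); at least 2
#'   groups with at least 2 tubes each.
#' @param posthoc compute Tukey HSD pairwise comparisons (default `TRUE`).
#' @param assumptions run Bartlett and Shapiro-Wilk checks (default `TRUE`).
#' @return list of class `"MortalityComparison"`: `insecticide`, `groups`
#'   (per-group mean mortality and transformed mean), `anova` (`F`, `df1`,
#'   `df2`, `p`), `tukey` (data.frame of pairs with `diff` and adjusted
#'   `p_adj`, `NULL` unless requested), `bartlett`, `shapiro`.
#' @export
mortalityAnova <- function(records, posthoc = TRUE, assumptions = TRUE) {
  records <- .check_records(records)
  grp <- factor(records$group, levels = sort(unique(as.character(records$group))))
  tubes <- table(grp)
  if (length(tubes) < 2L) stop("need at least 2 treatment groups")
  if (any(tubes < 2L))
    stop("group(s) with fewer than 2 replicate tubes: ",
         paste(names(tubes)[tubes < 2L], collapse = ", "))
  prop <- records$dead / records$exposed
  y <- arcsineTransform(prop)
  group_summary <- data.frame(
    group = levels(grp),
    n_tubes = as.integer(tubes),
    mean_mortality = as.numeric(tapply(prop, grp, mean)),
    mean_transformed = as.numeric(tapply(y, grp, mean)),
    stringsAsFactors = FALSE)
  k <- nlevels(grp)
  n <- length(y)
  degenerate <- sum((y - mean(y))^2) < 1e-24
  if (degenerate) {
    anova_res <- list(F = 0, df1 = k - 1L, df2 = n - k, p = 1)
    fit <- NULL
  } else {
    fit <- stats::aov(y ~ grp)
    tab <- summary(fit)[[1L]]
    anova_res <- list(F = tab$`F value`[1L], df1 = tab$Df[1L],
                      df2 = tab$Df[2L], p = tab$`Pr(>F)`[1L])
    if (!is.finite(anova_res$F)) {  # zero residual variance, groups differ
      anova_res$F <- Inf
      anova_res$p <- 0
    }
  }
  tukey <- NULL
  if (posthoc) {
    pairs <- utils::combn(levels(grp), 2L)
    if (degenerate || !is.finite(anova_res$F)) {
      p_adj <- rep(if (degenerate) 1 else 0, ncol(pairs))
      diffs <- apply(pairs, 2L, function(pr)
        group_summary$mean_transformed[match(pr[2L], group_summary$group)] -
        group_summary$mean_transformed[match(pr[1L], group_summary$group)])
      tukey <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                          diff = diffs, p_adj = p_adj,
                          stringsAsFactors = FALSE)
    } else {
      th <- stats::TukeyHSD(fit)$grp
      nm <- strsplit(rownames(th), "-", fixed = TRUE)
      tukey <- data.frame(group1 = vapply(nm, `[`, character(1), 2L),
                          group2 = vapply(nm, `[`, character(1), 1L),
                          diff = unname(th[, "diff"]),
                          p_adj = unname(th[, "p adj"]),
                          stringsAsFactors = FALSE)
    }
    rownames(tukey) <- NULL
  }
  checks <- list(bartlett = NULL, shapiro = NULL)
  if (assumptions) {
    resid <- if (is.null(fit)) y - stats::ave(y, grp) else stats::residuals(fit)
    checks <- assumptionChecks(y, grp, residuals = resid)
  }
  structure(list(
    insecticide = if ("insecticide" %in% names(records))
                    as.character(records$insecticide[1L]) else NA_character_,
    groups = group_summary, anova = anova_res, tukey = tukey,
    bartlett = checks$bartlett, shapiro = checks$shapiro),
    class = "MortalityComparison")
}

#' @export
print.MortalityComparison <- function(x, ...) {
  cat(sprintf("WHO-bioassay mortality comparison%s\n",
              if (is.na(x$insecticide)) "" else paste0(" [", x$insecticide, "]")))
  for (i in seq_len(nrow(x$groups)))
    cat(sprintf("  %-12s %d tubes, mean mortality %.1f%%\n",
                x$groups$group[i], x$groups$n_tubes[i],
                100 * x$groups$mean_mortality[i]))
  cat(sprintf("  ANOVA (arcsine-transformed): F(%d,%d) = %.3f, p = %.4g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  if (!is.null(x$tukey))
    for (i in seq_len(nrow(x$tukey)))
      cat(sprintf("    Tukey %s vs %s: p = %.4g\n", x$tukey$group1[i],
                  x$tukey$group2[i], x$tukey$p_adj[i]))
  if (!is.null(x$bartlett))
    cat(sprintf("  Bartlett: %s\n",
                if (is.na(x$bartlett$statistic)) x$bartlett$note
                else sprintf("K2 = %.3f, p = %.4g", x$bartlett$statistic,
                             x$bartlett$p)))
  if (!is.null(x$shapiro))
    cat(sprintf("  Shapiro-Wilk (residuals): %s\n",
                if (is.na(x$shapiro$statistic)) x$shapiro$note
                else sprintf("W = %.4f, p = %.4g", x$shapiro$statistic,
                             x$shapiro$p)))
  invisible(x)
}

#' ANOVA assumption checks
#'
#' Bartlett's test for homogeneity of variance across groups and the
#' Shapiro-Wilk normality test on the (supplied or within-group) residuals.
#' Degenerate all-equal data leaves Bartlett undefined, which is reported
#' as such rather than as an error.
#'
#' @param values numeric vector of transformed per-tube values.
#' @param groups factor/character of the same length with >= 2 levels.
#' @param residuals optional residual vector; defaults to within-group
#'   centred `values`.
#' @return list with `bartlett` (`statistic`, `df`, `p`, `note`) and
#'   `shapiro` (`statistic`, `p`, `note`).
#' @export
assumptionChecks <- function(values, groups, residuals = NULL) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("Bartlett needs at least 2 groups")
  if (length(values) < 3L) stop("Shapiro-Wilk needs total n >= 3")
  if (is.null(residuals)) residuals <- values - stats::ave(values, groups)
  vars <- tapply(values, groups, stats::var)
  bart <- if (all(vars == 0)) {
    list(statistic = NA_real_, df = nlevels(groups) - 1L, p = NA_real_,
         note = "undefined: zero variance in every group")
  } else if (any(vars == 0)) {
    list(statistic = NA_real_, df = nlevels(groups) - 1L, p = NA_real_,
         note = "undefined: a group has zero variance")
  } else {
    bt <- stats::bartlett.test(values, groups)
    list(statistic = unname(bt$statistic), df = unname(bt$parameter),
         p = bt$p.value, note = "")
  }
  shap <- if (length(unique(residuals)) < 3L) {
    list(statistic = NA_real_, p = NA_real_,
         note = "undefined: residuals (near-)constant")
  } else {
    st <- stats::shapiro.test(residuals)
    list(statistic = unname(st$statistic), p = st$p.value, note = "")
  }
  list(bartlett = bart, shapiro = shap)
}
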
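#' Fit a qPCR standard curve and estimate amplification efficiency
#'
#' Least-squares regression of Ct on log10(relative template quantity) over
#' a dilution series. Efficiency follows from the slope as
#' `(10^(-1/slope) - 1) * 100` percent; a perfect doubling chemistry gives
#' slope -1/log10(2) = -3.3219 and 100%. Curves outside the MIQE acceptable
#' range of 90-120% are flagged, as are non-negative slopes.
#'
#' @param dilution relative template quantities (e.g. `c(1, 0.2, 0.04,
#'   0.008)` for a 1, 1:5, 1:25, 1:125 series); at least 3 distinct
#'   positive values.
#' @param ct Ct values, one per dilution entry (replicates allowed by
#'   repeating dilution values).
#' @param gene gene label carried through to the result.
#' @return list of class `"EfficiencyResult"` with `gene`, `slope`,
#'   `intercept`, `r_squared`, `efficiency` (percent), `out_of_range`,
#'   `valid`.
#' @examples
#' fitStandardCurve(c(1, 0.2, 0.04, 0.008),
#'                  20 + log2(c(1, 5, 25, 125)), "CYP6M2")
#' @export
fitStandardCurve <- function(dilution, ct, gene = NA_character_) {
  dilution <- as.numeric(dilution)
  ct <- as.numeric(ct)
  stopifnot(length(dilution) == length(ct))
  if (any(dilution <= 0)) stop("dilution factors must be positive")
  if (length(unique(dilution)) < 3L)
    stop("need at least 3 distinct dilutions")
  fit <- stats::lm(ct ~ log10(dilution))
  slope <- unname(stats::coef(fit)[2L])
  eff <- (10^(-1 / slope) - 1) * 100
  valid <- is.finite(slope) && slope < 0
  structure(list(gene = gene, slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 efficiency = if (valid) eff else NA_real_,
                 out_of_range = valid && (eff < 90 || eff > 120),
                 valid = valid),
            class = "EfficiencyResult")
}

#' @export
print.EfficiencyResult <- function(x, ...) {
  cat(sprintf("Standard curve [%s]: slope %.4f, R2 %.4f, efficiency %s%s\n",
              x$gene, x$slope, x$r_squared,
              if (x$valid) sprintf("%.1f%%", x$efficiency) else "invalid",
              if (isTRUE(x$out_of_range)) " (OUT OF 90-120% RANGE)" else ""))
  invisible(x)
}

#' Normalize Ct values against housekeeping genes
#'
#' Technical replicates are averaged per (sample, gene); the normalized
#' value is `dCt = mean Ct(target) - mean over housekeepers of mean
#' Ct(housekeeper)` (arithmetic mean of Ct, i.e. geometric mean on the
#' expression scale). Every sample must have Ct values for all housekeeping
#' genes.
#'
#' @param ct long-format data.frame with columns `sample`, `group`, `gene`,
#'   `ct` (a `replicate` column, if present, indexes technical replicates).
#' @param housekeepers character vector of housekeeping gene ids (default
#'   `c("S7", "EF")`).
#' @return data.frame with one row per (sample, target gene): `sample`,
#'   `group`, `gene`, `ct_mean`, `hk_mean`, `dct`.
#' @export
deltaCt <- function(ct, housekeepers = c("S7", "EF")) {
  need <- c("sample", "group", "gene", "ct")
  if (!all(need %in% names(ct)))
    stop("'ct' must have columns: ", paste(need, collapse = ", "))
  if (any(ct$ct <= 0, na.rm = TRUE)) stop("Ct values must be positive")
  agg <- stats::aggregate(ct ~ sample + group + gene, data = ct, FUN = mean)
  hk <- agg[agg$gene %in% housekeepers, , drop = FALSE]
  for (s in unique(agg$sample)) {
    have <- hk$gene[hk$sample == s]
    miss <- setdiff(housekeepers, have)
    if (length(miss))
      stop("sample '", s, "' is missing housekeeper gene(s): ",
           paste(miss, collapse = ", "))
  }
  hk_mean <- tapply(hk$ct, hk$sample, mean)
  targets <- agg[!agg$gene %in% housekeepers, , drop = FALSE]
  out <- data.frame(sample = targets$sample, group = targets$group,
                    gene = targets$gene, ct_mean = targets$ct,
                    hk_mean = as.numeric(hk_mean[targets$sample]),
                    stringsAsFactors = FALSE)
  out$dct <- out$ct_mean - out$hk_mean
  out <- out[order(out$gene, out$group, out$sample), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relative expression by the delta-delta-Ct method
#'
#' For each target gene, subtracts the comparator group's mean dCt to get
#' per-replicate ddCt values and relative expression ratios `2^-ddCt`
#' (assuming 100% efficient, doubling chemistry, the method's own
#' assumption; see [fitStandardCurve()] for the QC gate). Group ratios are
#' summarized by the geometric mean of per-replicate ratios — equivalently
#' `2^-mean(ddCt)` — which makes the comparator group's summary exactly 1;
#' arithmetic mean and median summaries are available. Welch's t-test
#' compares the dCt values of each treatment group against the comparator.
#'
#' @param dct data.frame from [deltaCt()].
#' @param comparator comparator group label (default `"GFP"`).
#' @param summary `"geometric"` (default), `"arithmetic"` or `"median"`
#'   summary of per-replicate ratios.
#' @return list with `replicates` (per-sample ddCt and ratio) and `groups`
#'   (per gene x group: summarized `ratio`, `n`, and for non-comparator
#'   groups Welch `t`, `df`, `p` against the comparator).
#' @export
deltaDeltaCt <- function(dct, comparator = "GFP",
                         summary = c("geometric", "arithmetic", "median")) {
  summary <- match.arg(summary)
  if (!comparator %in% dct$group)
    stop("comparator group '", comparator, "' not present")
  reps <- NULL
  groups <- NULL
  for (g in unique(dct$gene)) {
    sub <- dct[dct$gene == g, , drop = FALSE]
    comp <- sub$dct[sub$group == comparator]
    if (!length(comp))
      stop("gene '", g, "' absent from comparator group")
    base <- mean(comp)
    sub$ddct <- sub$dct - base
    sub$ratio <- 2^(-sub$ddct)
    reps <- rbind(reps, sub)
    for (grp in unique(sub$group)) {
      ratios <- sub$ratio[sub$group == grp]
      val <- switch(summary,
                    geometric = 2^(-mean(sub$ddct[sub$group == grp])),
                    arithmetic = mean(ratios),
                    median = stats::median(ratios))
      row <- data.frame(gene = g, group = grp, ratio = val,
                        n = length(ratios), t = NA_real_, df = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE)
      if (grp != comparator && length(ratios) >= 2L && length(comp) >= 2L) {
        wt <- welchTest(sub$dct[sub$group == grp], comp)
        row$t <- wt$t; row$df <- wt$df; row$p <- wt$p
      }
      groups <- rbind(groups, row)
    }
  }
  rownames(reps) <- rownames(groups) <- NULL
  list(replicates = reps, groups = groups)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test with Satterthwaite degrees of freedom, the test
#' applied to dCt values between a knockdown group and its comparator. The
#' degenerate case of two constant, equal groups returns t = 0, p = 1 by
#' convention; two constant but different groups return p = 0.
#'
#' @param a,b numeric vectors, at least 2 values each.
#' @return list with `t`, `df`, `p`.
#' @export
welchTest <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
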
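#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two samples reporting the U statistic of the
#' first sample (so that U_a + U_b = n_a * n_b). The p-value is exact for
#' small untied samples and a tie-corrected normal approximation
#' otherwise, as implemented by \code{stats::wilcox.test}.
#'
#' @param a,b numeric vectors (nonempty).
#' @return list with \code{statistic} (U of \code{a}) and \code{p.value}.
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mannWhitney <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  p <- unname(wt$p.value)
  # all observations tied across both samples: no evidence either way
  if (is.nan(p)) p <- 1
  list(statistic = unname(wt$statistic), p.value = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: monotone, capped at 1,
#' returned in the input order.
#'
#' @param pvals numeric vector of p-values in \code{[0, 1]}.
#' @return adjusted p-values.
#' @export
bhAdjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Assumption-gated group comparison
#'
#' The study's decision tree: Shapiro-Wilk normality per group and a
#' median-centred Levene variance-homogeneity test are run at \code{alpha};
#' if either gate is significant the nonparametric branch is taken
#' (Kruskal-Wallis omnibus, all pairwise Mann-Whitney with
#' Benjamini-Hochberg adjustment), otherwise the parametric branch
#' (one-way ANOVA, or a mixed-measures ANOVA when \code{pairedWithin} is
#' given, with Tukey HSD or Dunnett post hoc). Tukey/Dunnett p-values are
#' family-adjusted by construction and reported as both raw and adjusted.
#'
#' @param samples either a named list of numeric vectors (one per group)
#'   or a data.frame with columns \code{group}, \code{value} and, for
#'   mixed designs, \code{subject} plus the \code{pairedWithin} column.
#' @param alpha gate significance level (default 0.05).
#' @param posthoc parametric post hoc family: \code{"tukey"} (default,
#'   all pairs) or \code{"dunnett"} (each group vs \code{control}).
#' @param control control group label for Dunnett; default the first group.
#' @param pairedWithin optional name of a within-subject factor column;
#'   switches the parametric omnibus to a mixed-measures ANOVA.
#' @return a [ComparisonReport-class].
#' @export
gatedCompare <- function(samples, alpha = 0.05,
                         posthoc = c("tukey", "dunnett"), control = NULL,
                         pairedWithin = NULL) {
  posthoc <- match.arg(posthoc)
  df <- asGroupData(samples)
  groups <- levels(df$group)
  if (length(groups) < 2L) stop("need at least 2 groups")
  ns <- table(df$group)
  if (any(ns < 3L)) {
    stop("every group needs n >= 3 (gates undefined): ",
      paste(names(ns)[ns < 3], collapse = ", "))
  }
  if (!all(is.finite(df$value))) stop("values must be finite")

  shap <- vapply(groups, function(g) {
    v <- df$value[df$group == g]
    if (stats::sd(v) == 0) 0 else stats::shapiro.test(v)$p.value
  }, numeric(1))
  lev <- car::leveneTest(value ~ group, data = df)[["Pr(>F)"]][1]
  if (is.na(lev)) lev <- 1  # zero spread everywhere: variances trivially equal
  nonpar <- any(shap < alpha) || lev < alpha

  pairs <- utils::combn(groups, 2L)
  if (nonpar) {
    kw <- stats::kruskal.test(value ~ group, data = df)
    pw <- apply(pairs, 2L, function(pr) {
      mw <- mannWhitney(df$value[df$group == pr[1]],
                        df$value[df$group == pr[2]])
      c(mw$statistic, mw$p.value)
    })
    pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
      statistic = pw[1, ], p = pw[2, ], p.adj = bhAdjust(pw[2, ]),
      method = "Mann-Whitney")
    omnibus <- list(method = "Kruskal-Wallis",
      statistic = unname(kw$statistic), p.value = kw$p.value)
    branch <- "nonparametric"
  } else {
    if (!is.null(pairedWithin)) {
      stopifnot(pairedWithin %in% names(df), "subject" %in% names(df))
      df$.w <- factor(df[[pairedWithin]])
      fit <- stats::aov(value ~ group * .w + Error(subject / .w), data = df)
      tab <- summary(fit)[["Error: subject"]][[1]]
      omnibus <- list(method = "mixed-measures ANOVA (group effect)",
        statistic = tab["group", "F value"],
        p.value = tab["group", "Pr(>F)"])
    } else {
      fit1 <- stats::aov(value ~ group, data = df)
      tab <- summary(fit1)[[1]]
      omnibus <- list(method = "one-way ANOVA",
        statistic = tab["group", "F value"],
        p.value = tab["group", "Pr(>F)"])
    }
    fitP <- stats::aov(value ~ group, data = df)
    if (posthoc == "tukey") {
      tk <- stats::TukeyHSD(fitP)$group
      nm <- strsplit(rownames(tk), "-", fixed = TRUE)
      pairwise <- data.frame(
        group1 = vapply(nm, `[`, "", 2L),
        group2 = vapply(nm, `[`, "", 1L),
        statistic = tk[, "diff"], p = tk[, "p adj"],
        p.adj = tk[, "p adj"], method = "Tukey")
    } else {
      if (!is.null(control)) df$group <- stats::relevel(df$group, control)
      fitD <- stats::aov(value ~ group, data = df)
      gl <- multcomp::glht(fitD, linfct = multcomp::mcp(group = "Dunnett"))
      sm <- summary(gl)
      nm <- strsplit(names(sm$test$coefficients), " - ", fixed = TRUE)
      pairwise <- data.frame(
        group1 = vapply(nm, `[`, "", 2L),
        group2 = vapply(nm, `[`, "", 1L),
        statistic = unname(sm$test$tstat),
        p = unname(as.numeric(sm$test$pvalues)),
        p.adj = unname(as.numeric(sm$test$pvalues)), method = "Dunnett")
    }
    branch <- "parametric"
  }
  rownames(pairwise) <- NULL
  new("ComparisonReport", branch = branch, gateShapiro = shap,
    gateLevene = as.numeric(lev), omnibus = omnibus, pairwise = pairwise,
    alpha = alpha)
}

asGroupData <- function(samples) {
  if (is.data.frame(samples)) {
    stopifnot(all(c("group", "value") %in% names(samples)))
    df <- samples
    df$group <- factor(df$group)
    if ("subject" %in% names(df)) df$subject <- factor(df$subject)
    return(df)
  }
  stopifnot(is.list(samples), !is.null(names(samples)))
  data.frame(
    group = factor(rep(names(samples), lengths(samples)),
                   levels = names(samples)),
    value = unlist(samples, use.names = FALSE))
}

#' Hand-vs-machine occupancy agreement
#'
#' Cell-wise comparison of two (session x zone) tables of seconds. The
#' normalized difference of a cell is \code{|hand - machine| / durationS}
#' as a percent of session length; the report carries the per-cell values,
#' their mean, and a paired t test across cells (statistic NA and p = 1
#' when all differences are zero, where the t statistic is undefined).
#'
#' @param hand,machine numeric matrices (sessions x zones) with matching
#'   dimnames, seconds per cell.
#' @param durationS session length in seconds used for normalization
#'   (default 120, the 2-minute trial).
#' @return an [AgreementReport-class].
#' @export
agreement <- function(hand, machine, durationS = 120) {
  hand <- as.matrix(hand); machine <- as.matrix(machine)
  if (!identical(dim(hand), dim(machine)) ||
      !identical(dimnames(hand), dimnames(machine))) {
    hk <- paste(rep(rownames(hand), ncol(hand)),
                rep(colnames(hand), each = nrow(hand)), sep = ":")
    mk <- paste(rep(rownames(machine), ncol(machine)),
                rep(colnames(machine), each = nrow(machine)), sep = ":")
    off <- union(setdiff(hk, mk), setdiff(mk, hk))
    stop("hand and machine tables do not share keys; offenders: ",
      paste(off, collapse = ", "))
  }
  diffPct <- abs(hand - machine) / durationS * 100
  cells <- data.frame(
    session = rep(rownames(hand) %||% seq_len(nrow(hand)), ncol(hand)),
    zone = rep(colnames(hand) %||% seq_len(ncol(hand)), each = nrow(hand)),
    hand = as.vector(hand), machine = as.vector(machine),
    diffPct = as.vector(diffPct))
  # constant differences (identical tables, uniform offsets) leave the
  # paired t statistic undefined; report p = 1 (no evidence of bias)
  pt <- tryCatch({
    tt <- stats::t.test(as.vector(hand), as.vector(machine), paired = TRUE)
    list(statistic = unname(tt$statistic), p.value = tt$p.value)
  }, error = function(e) list(statistic = NA_real_, p.value = 1))
  if (is.na(pt$p.value)) pt <- list(statistic = NA_real_, p.value = 1)
  new("AgreementReport", cells = cells,
    meanAbsErrorPct = mean(diffPct), pairedT = pt,
    durationS = as.numeric(durationS))
}

#' Seconds-per-zone table from a set of occupancy series
#'
#' @param occList named list of [ZoneOccupancySeries-class] objects.
#' @return numeric matrix sessions x zones.
#' @export
occupancyTable <- function(occList) {
  stopifnot(length(occList) > 0)
  m <- do.call(rbind, lapply(occList, secondsPerZone))
  rownames(m) <- names(occList) %||% seq_along(occList)
  m
}

#' Validated confusion-rate percentages
#'
#' @param fpPct,fnPct,tpPct,tnPct false-positive, false-negative,
#'   true-positive and true-negative rates, percent; must total 100
#'   within 0.5.
#' @return named numeric vector.
#' @export
confusionRates <- function(fpPct, fnPct, tpPct, tnPct) {
  r <- c(fp = fpPct, fn = fnPct, tp = tpPct, tn = tnPct)
  if (any(r < 0 | r > 100)) stop("rates must lie in [0, 100]")
  if (abs(sum(r) - 100) > 0.5) stop("rates must sum to 100 within 0.5")
  r
}

#' Recall, precision and accuracy from confusion rates
#'
#' recall = tp / (tp + fn), precision = tp / (tp + fp),
#' accuracy = (tp + tn) / (tp + tn + fp + fn), each as a percent rounded
#' to one decimal for reporting.
#'
#' @param rates output of [confusionRates()].
#' @return named numeric: \code{recall_pct}, \code{precision_pct},
#'   \code{accuracy_pct}.
#' @examples
#' confusionMetrics(confusionRates(6.8, 2.0, 84.0, 7.2))
#' # recall 97.7, precision 92.5
#' @export
confusionMetrics <- function(rates) {
  tp <- rates[["tp"]]; fp <- rates[["fp"]]
  fn <- rates[["fn"]]; tn <- rates[["tn"]]
  if (tp + fn == 0) stop("recall undefined: tp + fn = 0")
  if (tp + fp == 0) stop("precision undefined: tp + fp = 0")
  c(recall_pct = round(tp / (tp + fn) * 100, 1),
    precision_pct = round(tp / (tp + fp) * 100, 1),
    accuracy_pct = round((tp + tn) / (tp + tn + fp + fn) * 100, 1))
}

#' Day-trend simple linear regression
#'
#' Ordinary least squares of a measurement against test day.
#'
#' @param day numeric vector of days (at least 2 distinct values).
#' @param value numeric vector of measurements.
#' @return list with \code{slope}, \code{intercept}, \code{r.squared}
#'   (0 for a constant response, where the ratio is undefined).
#' @export
dailyTrend <- function(day, value) {
  stopifnot(length(day) == length(value))
  if (length(unique(day)) < 2L) stop("need at least 2 distinct days")
  fit <- stats::lm(value ~ day)
  ssTot <- sum((value - mean(value))^2)
  r2 <- if (ssTot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ssTot
  list(slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]), r.squared = r2)
}
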
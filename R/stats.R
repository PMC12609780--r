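# agreement_stats: method agreement (Pearson + Fisher-z CI, Bland-Altman)
# and longitudinal visit analysis (repeated-measures ANOVA with
# Tukey-adjusted pairwise comparisons).

#' Pearson correlation with Fisher-z confidence interval
#'
#' Sample correlation with the normal-theory interval on the Fisher
#' z scale, `tanh(atanh(r) +/- z * / sqrt(n - 3))`, and a two-sided p-value
#' from `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#'
#' @param x,y paired numeric vectors, n >= 4, finite, non-degenerate.
#' @param alpha two-sided level (default 0.05 for a 95% interval).
#' @return `list(n, r, ciLow, ciHigh, p)`.
#' @export
pearsonWithCi <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("x and y must be paired")
  ok <- is.finite(x) & is.finite(y)
  if (!all(ok)) stop("x and y must be finite")
  n <- length(x)
  if (n < 4L) stop("need at least 4 pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero-variance input: correlation undefined")
  r <- cor(x, y)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  crit <- qnorm(1 - alpha / 2)
  ci <- tanh(z + c(-1, 1) * crit / sqrt(n - 3))
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(n = n, r = r, ciLow = ci[1], ciHigh = ci[2], p = p)
}

#' Bland-Altman agreement analysis
#'
#' Paired differences d = x - y: bias = mean(d), 95% limits of agreement
#' bias +/- 1.96 sd(d) (sample sd). Pairs outside the limits are flagged.
#'
#' @param x,y paired numeric vectors, n >= 2.
#' @return `list(n, bias, sd, loaLow, loaHigh, means, diffs, outliers)` where
#'   `outliers` are the indices of pairs outside the limits.
#' @export
blandAltman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  loa <- bias + c(-1, 1) * 1.96 * s
  list(n = n, bias = bias, sd = s, loaLow = loa[1], loaHigh = loa[2],
       means = (x + y) / 2, diffs = d,
       outliers = which(d < loa[1] | d > loa[2]))
}

# complete-case long data for one plexus x method: subjects with every visit
completeCaseLong <- function(table, plexus, method) {
  validateMeasurements(table)
  sub <- table[table$plexus == plexus & table$method == method, , drop = FALSE]
  if (!nrow(sub)) stop("no records for plexus ", plexus, ", method ", method)
  sub$subjectEye <- paste(sub$subject_id, sub$eye, sep = ":")
  visits <- sort(unique(sub$visit))
  k <- length(visits)
  counts <- table(sub$subjectEye)
  complete <- names(counts)[counts == k]
  dropped <- length(counts) - length(complete)
  sub <- sub[sub$subjectEye %in% complete, , drop = FALSE]
  if (length(complete) < 2L)
    stop("need at least 2 subjects with all ", k, " visits (have ",
         length(complete), ")")
  list(df = data.frame(subject = factor(sub$subjectEye),
                       visit = factor(sub$visit, levels = visits),
                       y = sub$area_mm2),
       k = k, n = length(complete), dropped = dropped, visits = visits)
}

rmAnovaFit <- function(df) {
  fit <- aov(y ~ subject + visit, data = df)
  tab <- suppressWarnings(anova(fit))
  F <- tab["visit", "F value"]
  p <- tab["visit", "Pr(>F)"]
  ssTot <- sum(tab[, "Sum Sq"])
  # degenerate designs (no visit variation at all): F pinned to 0, p to 1
  if (ssTot == 0 || tab["visit", "Sum Sq"] / ssTot < 1e-10 ||
      !is.finite(F)) {
    F <- 0
    p <- 1
  }
  list(F = F, df1 = tab["visit", "Df"], df2 = tab["Residuals", "Df"],
       p = p, mse = tab["Residuals", "Mean Sq"])
}

#' Repeated-measures ANOVA across visits
#'
#' Two-way additive fixed-effects model (subject + visit) on complete cases
#' (subject-eyes observed at every visit; incomplete ones are dropped and
#' counted). The F statistic for the visit factor has df1 = k - 1 and
#' df2 = (n - 1)(k - 1).
#'
#' @param table a measurement table (see [validateMeasurements()]).
#' @param plexus `"SVP"`, `"IVP"` or `"DVP"`.
#' @param method `"script"`, `"ml"` or `"truth"`.
#' @return `list(F, df1, df2, p, nComplete, nDropped, visitMeans)`.
#' @export
rmAnova <- function(table, plexus, method) {
  cc <- completeCaseLong(table, plexus, method)
  fit <- rmAnovaFit(cc$df)
  means <- tapply(cc$df$y, cc$df$visit, mean)
  list(F = fit$F, df1 = fit$df1, df2 = fit$df2, p = fit$p,
       nComplete = cc$n, nDropped = cc$dropped,
       visitMeans = setNames(as.numeric(means), names(means)))
}

#' Tukey-adjusted pairwise visit comparisons
#'
#' For every visit pair the studentized-range statistic
#' q = |mean_i - mean_j| / sqrt(MSE / n) is referred to the studentized
#' range distribution with k groups and the residual degrees of freedom of
#' the repeated-measures model, giving familywise-adjusted p-values. All
#' C(k, 2) pairs are reported.
#'
#' @inheritParams rmAnova
#' @return A data.frame with `visit_i`, `visit_j`, `diff` (mean_j - mean_i),
#'   and `p_adj`.
#' @export
tukeyPairwise <- function(table, plexus, method) {
  cc <- completeCaseLong(table, plexus, method)
  fit <- rmAnovaFit(cc$df)
  means <- tapply(cc$df$y, cc$df$visit, mean)
  k <- cc$k; n <- cc$n
  pairs <- utils::combn(seq_len(k), 2)
  out <- data.frame(
    visit_i = cc$visits[pairs[1, ]],
    visit_j = cc$visits[pairs[2, ]],
    diff = as.numeric(means[pairs[2, ]] - means[pairs[1, ]]))
  q <- abs(out$diff) / sqrt(fit$mse / n)
  if (fit$mse <= 0) q <- ifelse(out$diff == 0, 0, Inf)  # perfect fit
  out$p_adj <- ptukey(q, nmeans = k, df = fit$df2, lower.tail = FALSE)
  attr(out, "mse") <- fit$mse
  attr(out, "df2") <- fit$df2
  out
}

#' Studentized range distribution function
#'
#' P(Q <= q) for the studentized range of k group means with the given
#' residual degrees of freedom (the reference distribution of the Tukey
#' adjustment). Monotone in q, 0 at q = 0 and 1 in the upper tail.
#'
#' @param q non-negative quantile.
#' @param k number of groups, >= 2.
#' @param df residual degrees of freedom, >= 1.
#' @return The cumulative probability.
#' @export
studentizedRangeCdf <- function(q, k, df) {
  if (any(q < 0)) stop("q must be >= 0")
  if (k < 2) stop("k must be >= 2")
  if (df < 1) stop("df must be >= 1")
  ptukey(q, nmeans = k, df = df)
}

#' Method-agreement report for one plexus
#'
#' Pairs script and ml areas by (subject, eye, visit) within a plexus,
#' pooling visits, and reports Pearson r with its Fisher-z interval together
#' with the Bland-Altman bias and limits of agreement (script - ml).
#'
#' @param table a measurement table containing both methods.
#' @param plexus `"SVP"`, `"IVP"` or `"DVP"`.
#' @param alpha level for the correlation interval.
#' @return `list(plexus, n, r, ciLow, ciHigh, p, bias, loaLow, loaHigh,
#'   outlierIds)`.
#' @export
agreementReport <- function(table, plexus, alpha = 0.05) {
  validateMeasurements(table)
  sub <- table[table$plexus == plexus, , drop = FALSE]
  s <- sub[sub$method == "script", ]
  m <- sub[sub$method == "ml", ]
  key <- function(d) paste(d$subject_id, d$eye, d$visit, sep = ":")
  ks <- key(s); km <- key(m)
  common <- intersect(ks, km)
  if (length(common) < 4L)
    stop("need at least 4 paired script/ml measurements for plexus ", plexus)
  xs <- s$area_mm2[match(common, ks)]
  xm <- m$area_mm2[match(common, km)]
  pc <- pearsonWithCi(xs, xm, alpha = alpha)
  ba <- blandAltman(xs, xm)
  list(plexus = plexus, n = pc$n, r = pc$r, ciLow = pc$ciLow,
       ciHigh = pc$ciHigh, p = pc$p, bias = ba$bias, loaLow = ba$loaLow,
       loaHigh = ba$loaHigh, outlierIds = common[ba$outliers])
}

#' Longitudinal report for one plexus and method
#'
#' Omnibus repeated-measures ANOVA across the four visits plus all
#' Tukey-adjusted pairwise visit comparisons.
#'
#' @inheritParams rmAnova
#' @return `list(plexus, method, F, df1, df2, p, nComplete, nDropped,
#'   visitMeans, pairwise)`.
#' @export
longitudinalReport <- function(table, plexus, method) {
  om <- rmAnova(table, plexus, method)
  pw <- tukeyPairwise(table, plexus, method)
  list(plexus = plexus, method = method, F = om$F, df1 = om$df1,
       df2 = om$df2, p = om$p, nComplete = om$nComplete,
       nDropped = om$nDropped, visitMeans = om$visitMeans,
       pairwise = pw)
}
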
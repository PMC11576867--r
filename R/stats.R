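## Nonparametric cohort statistics: mean +/- SE summaries, tie-corrected
## Kruskal-Wallis with Dunn's post-hoc z tests (Bonferroni by default),
## Wilcoxon signed-rank paired comparisons, Pearson chi-squared frequency
## comparisons, OLS regressions with R^2 and confidence bands, and a
## cohort-level report covering the standard side/sex/paired groupings.

#' Mean, standard error and n
#'
#' SE is the sample standard deviation (n - 1 denominator) over sqrt(n).
#'
#' @param values numeric vector, n >= 1.
#' @return Named vector (mean, se, n); `se` is 0 for n = 1.
#' @export
#' @examples
#' summarizeValues(c(1, 2, 3))  # mean 2, se 0.577
summarizeValues <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) stop("empty input")
  se <- if (n > 1L) stats::sd(values) / sqrt(n) else 0
  c(mean = mean(values), se = se, n = n)
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H (via [stats::kruskal.test()]) followed by
#' pairwise Dunn z statistics on the joint ranks,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j))` with the
#' tie term `T = sum(t^3 - t) / (12 (N - 1))`, two-sided normal p values and
#' a multiplicity adjustment over the compared pairs (Bonferroni by
#' default). If all values are identical the H statistic is 0 and p is 1.
#'
#' @param groups named list of numeric vectors (>= 2 groups).
#' @param adjust p-adjustment method for the Dunn comparisons, see
#'   [stats::p.adjust()].
#' @param alpha significance level for the `significant` flag.
#' @return List with `summary` (per-group mean/SE/n), `kw` (statistic, df,
#'   p.value) and `dunn` (data.frame of pairwise z, raw and adjusted p).
#' @export
#' @examples
#' g <- list(a = c(1, 3, 5), b = c(2, 4, 6), c = c(10, 11, 12))
#' kruskalDunn(g)$kw
kruskalDunn <- function(groups, adjust = "bonferroni", alpha = 0.05) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (any(vapply(groups, length, integer(1L)) < 1L))
    stop("every group needs at least one observation")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1L))),
              levels = names(groups))
  summary <- do.call(rbind, lapply(names(groups), function(nm) {
    s <- summarizeValues(groups[[nm]])
    data.frame(group = nm, mean = s[["mean"]], se = s[["se"]], n = s[["n"]],
               stringsAsFactors = FALSE)
  }))
  if (length(unique(x)) == 1L) {
    kw <- list(statistic = 0, df = length(groups) - 1L, p.value = 1)
  } else {
    kt <- stats::kruskal.test(x, g)
    kw <- list(statistic = unname(kt$statistic), df = unname(kt$parameter),
               p.value = kt$p.value)
  }
  ## Dunn pairwise z on joint ranks
  r <- rank(x)
  N <- length(x)
  tie <- table(x)
  tieTerm <- sum(tie^3 - tie) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  pairs <- utils::combn(names(groups), 2L)
  z <- p <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    sd2 <- (N * (N + 1) / 12 - tieTerm) * (1 / ns[[a]] + 1 / ns[[b]])
    z[i] <- if (sd2 > 0) (rbar[[a]] - rbar[[b]]) / sqrt(sd2) else 0
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  padj <- stats::p.adjust(p, method = adjust)
  dunn <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], z = z,
                     p = p, p.adjusted = padj,
                     significant = padj < alpha, stringsAsFactors = FALSE)
  list(summary = summary, kw = kw, dunn = dunn)
}

#' Paired comparison by Wilcoxon signed rank
#'
#' Two-sided by default; the exact signed-rank distribution is used for
#' n <= 25 when there are no ties or zero differences (the
#' [stats::wilcox.test()] rules). All-zero differences yield p = 1.
#'
#' @param right,left paired numeric vectors of equal length (pairing by
#'   position, e.g. by donor).
#' @param alternative passed to [stats::wilcox.test()].
#' @return List with `statistic` (V), `p.value`, `n` (pairs), `meanDiff`.
#' @export
pairedCompare <- function(right, left, alternative = "two.sided") {
  if (length(right) != length(left)) stop("paired vectors differ in length")
  keep <- !(is.na(right) | is.na(left))
  right <- right[keep]; left <- left[keep]
  if (!length(right)) stop("no complete pairs")
  d <- right - left
  if (all(d == 0))
    return(list(statistic = 0, p.value = 1, n = length(d), meanDiff = 0))
  wt <- suppressWarnings(stats::wilcox.test(right, left, paired = TRUE,
                                            alternative = alternative,
                                            exact = length(d) <= 25L))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       n = length(d), meanDiff = mean(d))
}

#' Pearson chi-squared test on a frequency table
#'
#' No continuity correction; degrees of freedom `(r - 1)(k - 1)`.
#'
#' @param tab matrix of non-negative counts (e.g. 2 x k).
#' @return List with `statistic`, `df`, `p.value`, `expected`.
#' @export
#' @examples
#' chiSquaredTest(rbind(c(10, 20), c(20, 10)))$statistic  # 20/3
chiSquaredTest <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in the frequency table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value, expected = ct$expected)
}

#' Ordinary least squares with R-squared and confidence band
#'
#' Fits `y ~ x` (or `y ~ log10(x)`) by OLS; R-squared equals the squared
#' Pearson correlation; the band is the pointwise 95% confidence interval
#' for the mean response on an even grid over the x range.
#'
#' @param x,y numeric vectors, n >= 3.
#' @param transform "identity" or "log10_x" (requires x > 0).
#' @param gridLength band grid size.
#' @return List with `slope`, `intercept`, `r.squared`, `band` (data.frame
#'   x, fit, lwr, upr on the transformed axis) and the fitted `model`.
#' @export
regressionR2 <- function(x, y, transform = c("identity", "log10_x"),
                         gridLength = 100L) {
  transform <- match.arg(transform)
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 observations")
  if (transform == "log10_x") {
    if (any(x <= 0)) stop("log10_x transform requires x > 0")
    x <- log10(x)
  }
  if (stats::var(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  grid <- data.frame(x = seq(min(x), max(x), length.out = gridLength))
  ci <- stats::predict(fit, grid, interval = "confidence", level = 0.95)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r.squared = summary(fit)$r.squared,
       band = data.frame(x = grid$x, fit = ci[, "fit"], lwr = ci[, "lwr"],
                         upr = ci[, "upr"]),
       model = fit)
}

## cohort measure vocabulary
.SECTION_MEASURES <- c("n_fascicles", "total_fascicle_area_um2",
                       "total_endoneurium_area_um2")
.FASCICLE_MEASURES <- c("fascicle_circumference_um", "fascicle_area_um2",
                        "endoneurium_area_um2", "endo_fascicle_ratio")

#' Long-format cohort table from synthetic or measured sections
#'
#' @param sections list of [`NerveCrossSection-class`] objects, or of
#'   `list(section = ...)` entries as returned by [generateCrossSection()].
#' @return Long-format data.frame (donor_id, side, sex, measure, value):
#'   section-level rows `n_fascicles`, `total_fascicle_area_um2`,
#'   `total_endoneurium_area_um2` (one per donor side) and fascicle-level
#'   rows `fascicle_circumference_um`, `fascicle_area_um2`,
#'   `endoneurium_area_um2`, `endo_fascicle_ratio` (one per fascicle).
#' @export
cohortFromSections <- function(sections) {
  rows <- list()
  for (entry in sections) {
    xs <- if (methods::is(entry, "NerveCrossSection")) entry else entry$section
    sums <- do.call(rbind, lapply(xs@fascicles, fascicleSummary))
    base <- data.frame(donor_id = xs@donorId, side = xs@side, sex = xs@sex,
                       stringsAsFactors = FALSE)
    add <- function(measure, value)
      rows[[length(rows) + 1L]] <<- cbind(
        base[rep(1L, length(value)), , drop = FALSE],
        data.frame(measure = measure, value = value,
                   stringsAsFactors = FALSE))
    add("n_fascicles", nrow(sums))
    add("total_fascicle_area_um2", sum(sums$fascicleArea))
    add("total_endoneurium_area_um2", sum(sums$endoneuriumArea))
    add("fascicle_circumference_um", sums$circumference)
    add("fascicle_area_um2", sums$fascicleArea)
    add("endoneurium_area_um2", sums$endoneuriumArea)
    add("endo_fascicle_ratio", sums$endoFascicleRatio)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic donor cohort with configurable group means
#'
#' Draws a long-format cohort table directly (no geometry): per-donor-side
#' fascicle counts from Poisson distributions with sex- and side-specific
#' means, per-fascicle circumference from side-specific lognormals,
#' endoneurium/fascicle ratios from side-specific truncated normals, and
#' areas consistent with the circumferences. The configured means are the
#' generator's ground truth for report-recovery tests.
#'
#' @param seed integer seed.
#' @param nMale,nFemale donor counts.
#' @param countMeans list with `male` and `female`, each `c(left=, right=)`
#'   Poisson means for fascicle counts.
#' @param ratioMeans `c(left=, right=)` mean endoneurium/fascicle ratios.
#' @return data.frame as in [cohortFromSections()], with the generating
#'   parameters attached as attribute `"truth"`.
#' @export
syntheticCohort <- function(seed = 1L, nMale = 14L, nFemale = 13L,
                            countMeans = list(
                              male = c(left = 2.9, right = 7.9),
                              female = c(left = 8.6, right = 17.1)),
                            ratioMeans = c(left = 0.81, right = 0.76)) {
  set.seed(seed)
  rows <- list()
  donors <- data.frame(
    donor_id = sprintf("D%02d", seq_len(nMale + nFemale)),
    sex = rep(c("male", "female"), c(nMale, nFemale)),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(donors))) {
    for (side in c("left", "right")) {
      nf <- max(1L, stats::rpois(1L, countMeans[[donors$sex[i]]][[side]]))
      circ <- if (side == "right") stats::rlnorm(nf, log(480), 1.2) else
        stats::rlnorm(nf, log(660), 1.1)
      ratio <- pmin(0.95, pmax(0.4,
        stats::rnorm(nf, ratioMeans[[side]], 0.05)))
      ## area consistent with circumference at a mildly non-circular shape
      area <- 0.9 * circ^2 / (4 * pi)
      endo <- ratio * area
      base <- data.frame(donor_id = donors$donor_id[i], side = side,
                         sex = donors$sex[i], stringsAsFactors = FALSE)
      add <- function(measure, value)
        rows[[length(rows) + 1L]] <<- cbind(
          base[rep(1L, length(value)), , drop = FALSE],
          data.frame(measure = measure, value = value,
                     stringsAsFactors = FALSE))
      add("n_fascicles", nf)
      add("total_fascicle_area_um2", sum(area))
      add("total_endoneurium_area_um2", sum(endo))
      add("fascicle_circumference_um", circ)
      add("fascicle_area_um2", area)
      add("endoneurium_area_um2", endo)
      add("endo_fascicle_ratio", ratio)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(countMeans = countMeans,
                             ratioMeans = ratioMeans)
  out
}

.measureBy <- function(cohort, measure, by) {
  sub <- cohort[cohort$measure == measure, , drop = FALSE]
  split(sub$value, sub[[by]])
}

#' Cohort report: side, sex and paired group statistics
#'
#' Emits every standard grouping for a bilateral donor cohort: right vs
#' left comparisons of the section-level measures (Kruskal-Wallis),
#' donor-paired right vs left comparisons (Wilcoxon signed rank), female vs
#' male fascicle counts (combined, left-only, right-only), and right vs
#' left comparisons of the individual-fascicle measures including the
#' endoneurium/fascicle ratio. Groupings whose measures or groups are
#' absent are flagged (`available = FALSE`) rather than dropped, and a
#' partial report is still produced.
#'
#' @param cohort long-format cohort table (see [cohortFromSections()]).
#' @param alpha significance level.
#' @return data.frame with one row per comparison: grouping, measure, group
#'   labels, n, mean and SE per group, test, statistic, p.value,
#'   significant, available.
#' @export
reproduceReport <- function(cohort, alpha = 0.05) {
  need <- c("donor_id", "side", "sex", "measure", "value")
  if (!all(need %in% names(cohort)))
    stop("cohort must have columns ", paste(need, collapse = ", "))
  rows <- list()
  addRow <- function(grouping, measure, g1, g2, s1, s2, test, statistic,
                     p, available = TRUE, note = "") {
    fmt <- function(s) if (is.null(s)) c(mean = NA_real_, se = NA_real_,
                                         n = NA_real_) else s
    s1 <- fmt(s1); s2 <- fmt(s2)
    rows[[length(rows) + 1L]] <<- data.frame(
      grouping = grouping, measure = measure, group1 = g1, group2 = g2,
      n1 = s1[["n"]], mean1 = s1[["mean"]], se1 = s1[["se"]],
      n2 = s2[["n"]], mean2 = s2[["mean"]], se2 = s2[["se"]],
      test = test, statistic = statistic, p.value = p,
      significant = !is.na(p) & p < alpha, available = available,
      note = note, stringsAsFactors = FALSE)
  }
  twoGroup <- function(grouping, measure, by, lv1, lv2, sub = NULL) {
    data <- if (is.null(sub)) cohort else sub
    g <- .measureBy(data, measure, by)
    if (!(measure %in% data$measure) || is.null(g[[lv1]]) ||
        is.null(g[[lv2]])) {
      addRow(grouping, measure, lv1, lv2, NULL, NULL, "kruskal_wallis",
             NA_real_, NA_real_, available = FALSE,
             note = "measure or group absent from cohort")
      return(invisible())
    }
    kd <- kruskalDunn(g[c(lv1, lv2)])
    addRow(grouping, measure, lv1, lv2,
           summarizeValues(g[[lv1]]), summarizeValues(g[[lv2]]),
           "kruskal_wallis", kd$kw$statistic, kd$kw$p.value)
  }

  for (m in .SECTION_MEASURES)
    twoGroup("side", m, "side", "right", "left")

  ## donor-paired right vs left
  for (m in .SECTION_MEASURES) {
    sub <- cohort[cohort$measure == m, , drop = FALSE]
    wide <- merge(sub[sub$side == "right", c("donor_id", "value")],
                  sub[sub$side == "left", c("donor_id", "value")],
                  by = "donor_id", suffixes = c(".right", ".left"))
    if (nrow(wide) < 1L) {
      addRow("paired_side", m, "right", "left", NULL, NULL,
             "wilcoxon_signed_rank", NA_real_, NA_real_, available = FALSE,
             note = "no donors with both sides")
      next
    }
    pc <- pairedCompare(wide$value.right, wide$value.left)
    addRow("paired_side", m, "right", "left",
           summarizeValues(wide$value.right),
           summarizeValues(wide$value.left),
           "wilcoxon_signed_rank", pc$statistic, pc$p.value)
  }

  ## sexual dimorphism of fascicle counts: combined and per side
  twoGroup("sex", "n_fascicles", "sex", "female", "male")
  for (sd in c("left", "right"))
    twoGroup(paste0("sex_", sd), "n_fascicles", "sex", "female", "male",
             sub = cohort[cohort$side == sd, , drop = FALSE])

  ## individual fascicles by side
  for (m in .FASCICLE_MEASURES)
    twoGroup("fascicle_side", m, "side", "right", "left")

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "methods") <- paste(
    "two-group comparisons: tie-corrected Kruskal-Wallis;",
    "paired: two-sided Wilcoxon signed rank (exact for n <= 25);",
    "alpha =", alpha)
  out
}
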
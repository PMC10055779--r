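#' Factorial general-linear-model F tests
#'
#' Three-way ANOVA of a per-sample response on the treatment factors
#' (biomass level x fertilizer x habitat) with all interactions, using
#' sequential sums of squares — on the balanced complete design this
#' coincides with every SS type. Native-soil samples (no factorial levels)
#' are excluded automatically. Unbalanced or incomplete designs are
#' rejected rather than silently approximated.
#'
#' @param response numeric vector, one value per design row (or the name of
#'   a covariate column in `design`)
#' @param design a [sample_design()]
#' @param factors which factors to include (default all three)
#' @return data.frame of class `anova_table`: `term`, `df`, `sum_sq`,
#'   `mean_sq`, `f`, `p` (residual row included)
#' @export
factorial_anova <- function(response, design,
                            factors = c("ismb", "fertilizer", "habitat")) {
  stopifnot(inherits(design, "sample_design"))
  if (is.character(response) && length(response) == 1L) {
    if (!response %in% names(design))
      stop_fmt("no covariate '%s' in design", response)
    response <- design[[response]]
  }
  if (length(response) != nrow(design))
    stop_fmt("response length != number of samples")
  keep <- design$ismb != "native"
  y <- response[keep]
  df <- droplevels(as.data.frame(design)[keep, factors, drop = FALSE])
  if (anyNA(y)) stop_fmt("missing response values")

  cells <- interaction(df, drop = FALSE)
  tab <- table(cells)
  if (any(tab == 0L)) stop_fmt("empty design cell: %s", names(tab)[tab == 0][1L])
  if (any(tab < 2L)) stop_fmt("design cell '%s' has < 2 replicates",
                              names(tab)[tab < 2][1L])
  if (length(unique(tab)) != 1L)
    stop_fmt("unbalanced design (cell sizes %s)",
             paste(sort(unique(tab)), collapse = ", "))

  dat <- cbind(df, .y = y)
  form <- stats::as.formula(paste(".y ~", paste(factors, collapse = " * ")))
  if (var(y) == 0) {
    # constant response: define all F = 0, p = 1
    fit <- suppressWarnings(stats::aov(form, data = dat))
    an <- suppressWarnings(stats::anova(fit))
    out <- data.frame(term = gsub(" ", "", rownames(an)),
                      df = an$Df, sum_sq = 0, mean_sq = 0,
                      f = c(rep(0, nrow(an) - 1L), NA),
                      p = c(rep(1, nrow(an) - 1L), NA),
                      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    an <- stats::anova(stats::aov(form, data = dat))
    out <- data.frame(term = gsub(" ", "", rownames(an)),
                      df = an$Df, sum_sq = an$`Sum Sq`,
                      mean_sq = an$`Mean Sq`, f = an$`F value`,
                      p = an$`Pr(>F)`,
                      stringsAsFactors = FALSE, row.names = NULL)
  }
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Pairwise correlation screen between two variable sets
#'
#' Pearson or Spearman correlation with a two-sided t-approximation p-value
#' for every (column of `x_table`) x (column of `y_table`) pair; a least
#' squares slope (`y` on `x`) is reported alongside. Pairs with a constant
#' variable are flagged missing.
#'
#' @param x_table,y_table numeric matrices or data.frames, observations in
#'   rows, variables in named columns (>= 4 complete rows)
#' @param method `"pearson"` or `"spearman"`
#' @return data.frame of class `correlation_screen`: `var_x`, `var_y`,
#'   `estimate`, `p`, `slope`, `n`
#' @export
correlation_screen <- function(x_table, y_table,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x_table <- as.data.frame(x_table)
  y_table <- as.data.frame(y_table)
  if (nrow(x_table) != nrow(y_table))
    stop_fmt("x and y tables must have the same number of observations")
  out <- list()
  for (vx in names(x_table)) {
    for (vy in names(y_table)) {
      x <- x_table[[vx]]; y <- y_table[[vy]]
      ok <- stats::complete.cases(x, y)
      n <- sum(ok)
      if (n < 4L) stop_fmt("pair (%s, %s): fewer than 4 paired observations",
                           vx, vy)
      xo <- x[ok]; yo <- y[ok]
      if (sd(xo) == 0 || sd(yo) == 0) {
        est <- NA_real_; pv <- NA_real_; slope <- NA_real_
      } else {
        ct <- suppressWarnings(
          stats::cor.test(xo, yo, method = method, exact = FALSE))
        est <- unname(ct$estimate)
        # two-sided t approximation (also for Spearman)
        tt <- est * sqrt((n - 2) / (1 - est^2))
        pv <- if (abs(est) >= 1) 0 else 2 * pt(-abs(tt), df = n - 2)
        slope <- stats::cov(xo, yo) / stats::var(xo)
      }
      out[[length(out) + 1L]] <- data.frame(
        var_x = vx, var_y = vy, estimate = est, p = pv, slope = slope,
        n = n, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("correlation_screen", "data.frame")
  res
}

#' Agronomic efficiency of applied nitrogen
#'
#' `(yield_fert - yield_nofert) / n_applied`, the yield gain over the
#' unfertilized control per unit of nitrogen applied (kg/kg when yields are
#' in kg and N in kg).
#'
#' @param yield_fert yield under fertilization
#' @param yield_nofert yield of the no-fertilizer control
#' @param n_applied amount of N applied (> 0)
#' @return agronomic efficiency (vectorized)
#' @export
agronomic_efficiency <- function(yield_fert, yield_nofert, n_applied) {
  if (any(n_applied <= 0)) stop_fmt("n_applied must be > 0")
  (yield_fert - yield_nofert) / n_applied
}
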
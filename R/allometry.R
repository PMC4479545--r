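# ANCOVA homogeneity-of-slopes test for allometric scaling differences
# among delimited species (e.g., head size on rattle size).

#' Test heterogeneity of allometric slopes among groups
#'
#' Both variables are log10-transformed (allometric scaling is linear on
#' log-log axes) and a full model with per-group slope and intercept is
#' compared against a reduced model with a common slope:
#' F = ((RSS_r - RSS_f)/df1) / (RSS_f/df2) with df1 = g - 1 and
#' df2 = n - 2g.
#'
#' @param x predictor sizes (e.g., rattle size), positive.
#' @param y response sizes (e.g., head size), positive.
#' @param group group labels (factor or vector), at least 2 groups with 3
#'   or more points each.
#' @param log_transform log10-transform both variables (default TRUE).
#' @return An object of class \code{slope_test}: n, g, per-group slopes and
#'   intercepts, RSS_full, RSS_reduced, F, df1, df2, p.
#' @export
slope_heterogeneity <- function(x, y, group, log_transform = TRUE) {
  group <- factor(group)
  g <- nlevels(group)
  n <- length(x)
  if (g < 2) cd_stop("need at least 2 groups", "group_size")
  if (any(table(group) < 3)) cd_stop("every group needs at least 3 points",
                                     "group_size")
  if (log_transform) {
    if (any(x <= 0) || any(y <= 0)) {
      cd_stop("sizes must be positive for log transformation", "domain")
    }
    x <- log10(x); y <- log10(y)
  }
  xvar <- tapply(x, group, stats::var)
  if (any(xvar == 0)) cd_stop("zero x-variance within a group", "degenerate")

  full <- stats::lm(y ~ group + x:group)
  reduced <- stats::lm(y ~ group + x)
  rss_f <- sum(stats::resid(full)^2)
  rss_r <- sum(stats::resid(reduced)^2)
  df1 <- g - 1
  df2 <- n - 2 * g
  if (df2 < 1) cd_stop("too few points for the full model", "group_size")
  Fstat <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)

  co <- stats::coef(full)
  slopes <- co[grep("^group.*:x$|^x:group|:x$", names(co))]
  slopes <- stats::setNames(as.numeric(slopes), levels(group))
  intercepts <- vapply(levels(group), function(l) {
    b <- co["(Intercept)"]
    extra <- co[paste0("group", l)]
    as.numeric(b + ifelse(is.na(extra), 0, extra))
  }, numeric(1))

  structure(list(n = n, g = g, slopes = slopes, intercepts = intercepts,
                 RSS_full = rss_f, RSS_reduced = rss_r,
                 F = Fstat, df1 = df1, df2 = df2, p = p),
            class = "slope_test")
}

#' @export
print.slope_test <- function(x, ...) {
  cat(sprintf("Homogeneity of slopes: F(%d, %d) = %.3f, p = %.3g\n",
              x$df1, x$df2, x$F, x$p))
  cat("  per-group slopes:",
      paste(sprintf("%s=%.3f", names(x$slopes), x$slopes), collapse = " "),
      "\n")
  invisible(x)
}
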
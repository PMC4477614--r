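# Nitrogen-response models and association statistics: broken-stick
# (continuous two-segment) regression, Pearson correlation with
# significance, stratified correlations, and tolerance ranking.

#' Fit a continuous two-segment (broken-stick) regression
#'
#' Least-squares piecewise-linear fit with a single breakpoint and the two
#' segments constrained to meet at it.  The breakpoint is chosen by grid
#' search over the interior observed x values (or a supplied grid); for each
#' candidate the segments are solved in closed form as the linear model
#' \code{y ~ x + max(x - c, 0)}.  Ties in residual sum of squares are broken
#' toward the smaller breakpoint.  With fewer than 4 distinct x values the
#' fit falls back to a single line (flagged).
#'
#' @param x predictor (e.g. N rate, kg/ha).
#' @param y response (e.g. crop senescence index, %).
#' @param breakpoints optional candidate breakpoint grid; default: interior
#'   distinct observed x values.
#' @param fixed_breakpoint optional known breakpoint (skips the search).
#' @return an object of class \code{broken_stick} with components
#'   \code{breakpoint}, \code{slope_low}, \code{slope_high},
#'   \code{intercept} (value of the low segment at x = 0), \code{rss},
#'   \code{fitted.values}, \code{residuals}, \code{slope_pct_of_range}
#'   (per-segment drop as % of the fitted response range, a diagnostic
#'   mirroring slope-percentage summaries), \code{single_line},
#'   \code{candidates}, and the data.
#' @export
fit_broken_stick <- function(x, y, breakpoints = NULL,
                             fixed_breakpoint = NULL) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  ux <- sort(unique(x))
  if (length(ux) < 4 && is.null(fixed_breakpoint)) {
    warning("fewer than 4 distinct x values; fitting a single line")
    fit <- stats::lm(y ~ x)
    co <- stats::coef(fit)
    obj <- list(breakpoint = NA_real_, slope_low = unname(co[2]),
                slope_high = unname(co[2]), intercept = unname(co[1]),
                rss = sum(stats::resid(fit)^2),
                fitted.values = stats::fitted(fit),
                residuals = stats::resid(fit),
                slope_pct_of_range = c(low = NA_real_, high = NA_real_),
                single_line = TRUE, candidates = numeric(0), x = x, y = y)
    class(obj) <- "broken_stick"
    return(obj)
  }
  cand <- if (!is.null(fixed_breakpoint)) fixed_breakpoint
          else if (!is.null(breakpoints)) sort(breakpoints)
          else ux[-c(1, length(ux))]
  best <- NULL
  for (cp in cand) {
    xb <- pmax(x - cp, 0)
    fit <- stats::lm(y ~ x + xb)
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(cp = cp, fit = fit, rss = rss)
    }
  }
  co <- stats::coef(best$fit)
  co[is.na(co)] <- 0
  fitted <- stats::fitted(best$fit)
  rng <- diff(range(fitted))
  lo_drop <- abs(co[["x"]]) * (best$cp - min(x))
  hi_drop <- abs(co[["x"]] + co[["xb"]]) * (max(x) - best$cp)
  obj <- list(breakpoint = best$cp,
              slope_low = unname(co[["x"]]),
              slope_high = unname(co[["x"]] + co[["xb"]]),
              intercept = unname(co[["(Intercept)"]]),
              rss = best$rss,
              fitted.values = fitted,
              residuals = stats::resid(best$fit),
              slope_pct_of_range = c(
                low = if (rng > 0) 100 * lo_drop / rng else NA_real_,
                high = if (rng > 0) 100 * hi_drop / rng else NA_real_),
              single_line = FALSE, candidates = cand, x = x, y = y)
  class(obj) <- "broken_stick"
  obj
}

#' @export
print.broken_stick <- function(x, ...) {
  if (x$single_line) {
    cat(sprintf("<broken_stick> single-line fallback: slope %.4g, rss %.4g\n",
                x$slope_low, x$rss))
  } else {
    cat(sprintf(
      "<broken_stick> breakpoint %.4g; slopes %.4g (below) / %.4g (above); rss %.4g\n",
      x$breakpoint, x$slope_low, x$slope_high, x$rss))
  }
  invisible(x)
}

#' @export
coef.broken_stick <- function(object, ...) {
  c(intercept = object$intercept, breakpoint = object$breakpoint,
    slope_low = object$slope_low, slope_high = object$slope_high)
}

#' @export
fitted.broken_stick <- function(object, ...) object$fitted.values

#' @export
residuals.broken_stick <- function(object, ...) object$residuals

#' @export
predict.broken_stick <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x
       else if (is.list(newdata)) newdata$x else newdata
  if (object$single_line) return(object$intercept + object$slope_low * x)
  object$intercept + object$slope_low * pmin(x, object$breakpoint) +
    object$slope_high * pmax(x - object$breakpoint, 0)
}

#' @export
summary.broken_stick <- function(object, ...) {
  n <- length(object$x)
  cat("Continuous two-segment least-squares fit\n")
  print(object)
  cat(sprintf("  n = %d, residual SD = %.4g\n", n,
              sqrt(object$rss / max(n - 4, 1))))
  if (!object$single_line)
    cat(sprintf("  segment drop as %% of fitted range: %.1f%% (below) / %.1f%% (above)\n",
                object$slope_pct_of_range[["low"]],
                object$slope_pct_of_range[["high"]]))
  invisible(object)
}

#' @export
plot.broken_stick <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = "N rate (kg/ha)", ylab = "response",
                 pch = 16, ...)
  ox <- seq(min(x$x), max(x$x), length.out = 200)
  graphics::lines(ox, predict(x, ox), col = "firebrick", lwd = 2)
  if (!x$single_line)
    graphics::abline(v = x$breakpoint, lty = 3, col = "grey40")
  invisible(x)
}

#' Pearson correlation with significance and confidence interval
#'
#' Product-moment correlation with a two-sided p-value from the t transform
#' (n - 2 df) and a 95% confidence interval by Fisher's z.
#'
#' @param a,b paired numeric vectors; pairs with missing members excluded.
#' @param conf confidence level (default 0.95).
#' @return list of class \code{correlation_result}: \code{r}, \code{n},
#'   \code{p_value}, \code{ci95} (length-2), \code{stars} (significance at
#'   0.05/0.01/0.001).
#' @export
pearson <- function(a, b, conf = 0.95) {
  stopifnot(length(a) == length(b))
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: zero variance")
  r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  z <- atanh(r); se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- tanh(c(z - q * se, z + q * se))
  stars <- if (p <= 0.001) "***" else if (p <= 0.01) "**"
           else if (p <= 0.05) "*" else "NS"
  structure(list(r = r, n = n, p_value = p, ci95 = ci, stars = stars),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f (n = %d), 95%% CI [%.3f, %.3f], p = %.3g %s\n",
              x$r, x$n, x$ci95[1], x$ci95[2], x$p_value, x$stars))
  invisible(x)
}

#' Correlations between trait pairs within N-rate strata
#'
#' One Pearson correlation per (variable pair, stratum); rows with an
#' undefined member are excluded pairwise.  Strata with fewer than 3
#' complete pairs are flagged and left unestimated.
#'
#' @param data data.frame holding the variables and an \code{n_rate} column
#'   (e.g. an index table merged with yields).
#' @param pairs list of 2-element character vectors of column names.
#' @param strata named list of N-rate subsets; a \code{NULL} element (or the
#'   name \code{"all"}) uses all rows.
#' @return data.frame with one row per pair x stratum: \code{var_a},
#'   \code{var_b}, \code{stratum}, \code{n}, \code{r}, \code{p_value},
#'   \code{ci_lo}, \code{ci_hi}, \code{stars}, \code{flagged}.
#' @export
correlate_by_stratum <- function(data, pairs,
                                 strata = list(all = NULL)) {
  rows <- list()
  for (pp in pairs) {
    for (sname in names(strata)) {
      sel <- if (is.null(strata[[sname]])) rep(TRUE, nrow(data))
             else data$n_rate %in% strata[[sname]]
      a <- data[[pp[1]]][sel]; b <- data[[pp[2]]][sel]
      ok <- sum(is.finite(a) & is.finite(b))
      if (ok < 3) {
        rows[[length(rows) + 1]] <- data.frame(
          var_a = pp[1], var_b = pp[2], stratum = sname, n = ok,
          r = NA_real_, p_value = NA_real_, ci_lo = NA_real_,
          ci_hi = NA_real_, stars = NA_character_, flagged = TRUE,
          stringsAsFactors = FALSE)
      } else {
        ct <- pearson(a, b)
        rows[[length(rows) + 1]] <- data.frame(
          var_a = pp[1], var_b = pp[2], stratum = sname, n = ct$n,
          r = ct$r, p_value = ct$p_value, ci_lo = ct$ci95[1],
          ci_hi = ct$ci95[2], stars = ct$stars, flagged = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Rank hybrids for low-N tolerance
#'
#' Orders hybrids by ascending mean nitrogen stress index over the selected
#' (low) N rates: the least-stressed hybrid at low N ranks first.  Ties are
#' broken by hybrid id.
#'
#' @param index_table an \code{index_table} (must contain \code{hybrid_id},
#'   \code{n_rate}, \code{nsi}; \code{tolerance_class} is carried through if
#'   present).
#' @param rates N rates over which to average (default \code{c(0, 10, 20)}).
#' @return data.frame ordered by rank: \code{rank}, \code{hybrid_id},
#'   \code{mean_nsi}, \code{n_plots} (+ \code{tolerance_class}).
#' @export
rank_genotypes <- function(index_table, rates = c(0, 10, 20)) {
  d <- index_table[index_table$n_rate %in% rates & !is.na(index_table$nsi), ]
  if (length(unique(d$hybrid_id)) < 2) stop("need at least 2 hybrids")
  agg <- do.call(rbind, lapply(split(d, d$hybrid_id), function(g) {
    data.frame(hybrid_id = g$hybrid_id[1],
               tolerance_class = if ("tolerance_class" %in% names(g))
                 g$tolerance_class[1] else NA_character_,
               mean_nsi = mean(g$nsi), n_plots = nrow(g),
               stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$mean_nsi, agg$hybrid_id), ]
  agg <- cbind(rank = seq_len(nrow(agg)), agg)
  rownames(agg) <- NULL
  agg
}
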
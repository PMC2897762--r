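lowess_pass <- function(xs, ys, h, base_w) {
  # xs sorted ascending; returns fitted value at each xs by local linear WLS
  n <- length(xs)
  fitted <- numeric(n)
  for (i in seq_len(n)) {
    lo <- findInterval(xs[i] - h, xs) + 1L
    hi <- findInterval(xs[i] + h, xs)
    idx <- lo:hi
    w <- base_w[idx]
    if (sum(w > 0) < 2L || length(unique(xs[idx][w > 0])) < 2L) {
      # degenerate window: fall back to the nearest points carrying weight
      ord <- order(abs(xs - xs[i]))
      pick <- ord[base_w[ord] > 0]
      idx <- head(pick, max(2L, length(idx)))
      w <- base_w[idx]
    }
    d <- abs(xs[idx] - xs[i]) / h
    tri <- pmax(1 - pmin(d, 1)^3, 0)^3
    tri[d >= 1] <- 1e-6                       # fallback points beyond window
    w <- w * tri
    sw <- sum(w)
    if (sw <= 0) { fitted[i] <- mean(ys[idx]); next }
    xb <- sum(w * xs[idx]) / sw
    yb <- sum(w * ys[idx]) / sw
    sxx <- sum(w * (xs[idx] - xb)^2)
    if (sxx <= .Machine$double.eps * sw) {
      fitted[i] <- yb
    } else {
      b <- sum(w * (xs[idx] - xb) * (ys[idx] - yb)) / sxx
      fitted[i] <- yb + b * (xs[i] - xb)
    }
  }
  fitted
}

#' Robust span-based Lowess fit
#'
#' Locally linear smoothing in which the smoothing window is a fixed
#' fraction of the span of the predictor (`window_frac` times
#' `max(x) - min(x)`), not a fraction of the number of points as in
#' [stats::lowess()]. Points within the window receive tricube weights. The
#' fit is made robust in two passes: after an initial fit, points whose
#' residual exceeds `outlier_sd` standard deviations of the residuals get
#' zero weight and the curve is refit once.
#'
#' @param x,y Numeric vectors (>= 10 points, non-constant `x`); pairs with
#'   `NA` in either are dropped.
#' @param window_frac Window width as a fraction of the predictor span
#'   (default 0.1).
#' @param outlier_sd Outlier cutoff in residual standard deviations
#'   (default 6).
#' @return A `robust_lowess` object: `x`, `y`, `fitted`, `residual`,
#'   `outlier` (logical), `window_frac`, `bandwidth` (half-window in x
#'   units).
#' @export
robust_lowess <- function(x, y, window_frac = 0.1, outlier_sd = 6) {
  ok <- !is.na(x) & !is.na(y)
  x0 <- x[ok]; y0 <- y[ok]
  if (length(x0) < 10) abort("robust_lowess() needs at least 10 points.")
  span <- diff(range(x0))
  if (span == 0) abort("constant predictor: degenerate fit.")
  if (window_frac <= 0 || window_frac > 1) abort("`window_frac` must be in (0, 1].")
  h <- window_frac * span / 2
  o <- order(x0)
  xs <- x0[o]; ys <- y0[o]
  f1 <- lowess_pass(xs, ys, h, rep(1, length(xs)))
  r1 <- ys - f1
  s <- sd(r1)
  outlier <- if (is.finite(s) && s > 0) abs(r1) > outlier_sd * s else
    rep(FALSE, length(r1))
  f2 <- if (any(outlier)) lowess_pass(xs, ys, h, as.numeric(!outlier)) else f1
  # back to input order (of the NA-complete subset)
  inv <- order(o)
  structure(list(x = x0, y = y0, fitted = f2[inv], residual = (ys - f2)[inv],
                 outlier = outlier[inv], window_frac = window_frac,
                 bandwidth = h, complete = ok),
            class = "robust_lowess")
}

#' @export
print.robust_lowess <- function(x, ...) {
  cat(sprintf("Robust Lowess fit: %d points, window %.0f%% of span, %d outliers down-weighted\n",
              length(x$x), 100 * x$window_frac, sum(x$outlier)))
  invisible(x)
}

#' @export
tidy.robust_lowess <- function(x, ...) {
  obj <- x
  tibble(x = obj$x, y = obj$y, fitted = obj$fitted, residual = obj$residual,
         outlier = obj$outlier)
}

#' @export
glance.robust_lowess <- function(x, ...) {
  tibble(n = length(x$x), n_outliers = sum(x$outlier),
         bandwidth = x$bandwidth,
         percent_variance = percent_variance(x$y, x$fitted))
}

#' @export
autoplot.robust_lowess <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outlier), alpha = 0.5,
                        size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red",
                       linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "orange")) +
    ggplot2::labs(x = "predictor", y = "response", colour = "outlier")
}

#' Percent of variance explained by a fit
#'
#' `(1 - var(y - fitted) / var(y)) * 100`: the share of the response
#' variance removed by subtracting the fitted values.
#'
#' @param y Observed values. @param fitted Fitted values (same length).
#' @return Percent (scalar; at most 100).
#' @export
percent_variance <- function(y, fitted) {
  stopifnot(length(y) == length(fitted))
  ok <- !is.na(y) & !is.na(fitted)
  vy <- var(y[ok])
  if (!is.finite(vy) || vy == 0) abort("var(y) is zero: percent undefined.")
  (1 - var(y[ok] - fitted[ok]) / vy) * 100
}

#' Successive variance partitioning across ordered determinants
#'
#' Fits the response against the first determinant with [robust_lowess()],
#' takes the residual, fits it against the next determinant, and so on.
#' Per-step percentages are referenced to the variance of the original
#' response (so the steps sum to the cumulative percent); each step's
#' percentage relative to its own input variance is reported alongside.
#'
#' @param y Response (e.g. 5' NFR occupancy per gene).
#' @param determinants Named list (or data frame) of numeric predictors, in
#'   fitting order (e.g. expression, Poly(dA:dT) strength, GRF affinity).
#' @param window_frac,outlier_sd Passed to [robust_lowess()].
#' @return A `variance_partition` object; `tidy()` gives one row per step
#'   with `step_percent`, `step_percent_local` and `cumulative_percent`.
#' @export
successive_partition <- function(y, determinants, window_frac = 0.1,
                                 outlier_sd = 6) {
  determinants <- as.list(determinants)
  if (length(determinants) == 0) abort("need at least one determinant.")
  if (is.null(names(determinants)) || any(names(determinants) == ""))
    names(determinants) <- paste0("d", seq_along(determinants))
  ok <- !is.na(y) & Reduce(`&`, lapply(determinants, function(d) !is.na(d)))
  y0 <- y[ok]
  var0 <- var(y0)
  if (!is.finite(var0) || var0 == 0) abort("var(y) is zero.")
  r <- y0
  rows <- purrr::map_dfr(names(determinants), function(nm) {
    d <- determinants[[nm]][ok]
    fit <- robust_lowess(d, r, window_frac, outlier_sd)
    r_new <- r - fit$fitted
    row <- tibble(determinant = nm,
                  step_percent = (var(r) - var(r_new)) / var0 * 100,
                  step_percent_local = (1 - var(r_new) / var(r)) * 100,
                  cumulative_percent = (1 - var(r_new) / var0) * 100)
    r <<- r_new
    row
  })
  structure(list(steps = rows, n = sum(ok), var_y = var0),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf("Variance partition over %d genes:\n", x$n))
  print(as.data.frame(x$steps), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.variance_partition <- function(x, ...) x$steps

#' @export
glance.variance_partition <- function(x, ...) {
  tibble(n = x$n, n_determinants = nrow(x$steps),
         total_percent = tail(x$steps$cumulative_percent, 1))
}

#' @export
autoplot.variance_partition <- function(object, ...) {
  d <- object$steps
  d$determinant <- factor(d$determinant, levels = d$determinant)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$determinant,
                                  y = .data$step_percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative_percent, group = 1),
                       colour = "black") +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative_percent)) +
    ggplot2::labs(y = "percent of variance explained", x = NULL)
}

#' K-S enrichments on expression-corrected features
#'
#' Removes the expression-explainable component of each chromatin feature by
#' subtracting a [robust_lowess()] fit of the feature against expression,
#' then recomputes gene-set K-S enrichments on the residuals. Enrichments
#' that survive this correction reflect chromatin signal beyond what
#' expression level predicts.
#'
#' @param data Tibble with `gene_id`, feature columns and an expression
#'   column.
#' @param sets Gene sets (`set_id`, `gene_id`).
#' @param features Feature columns to correct and test.
#' @param expression_col Name of the expression column (default
#'   `"expression"`).
#' @param min_size,q As in [ks_enrichment_table()].
#' @param window_frac,outlier_sd As in [robust_lowess()].
#' @return Long enrichment tibble as from [ks_enrichment_table()], computed
#'   on residual features.
#' @export
expression_corrected_enrichment <- function(data, sets, features,
                                            expression_col = "expression",
                                            min_size = 10L, q = 0.05,
                                            window_frac = 0.1,
                                            outlier_sd = 6) {
  ex <- data[[expression_col]]
  corrected <- data["gene_id"]
  for (f in features) {
    v <- data[[f]]
    ok <- !is.na(v) & !is.na(ex)
    res <- rep(NA_real_, nrow(data))
    if (sum(ok) >= 10) {
      fit <- robust_lowess(ex[ok], v[ok], window_frac, outlier_sd)
      res[ok] <- fit$residual
    }
    corrected[[f]] <- res
  }
  ks_enrichment_table(corrected, sets, features, min_size, q)
}
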
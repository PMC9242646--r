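#' Grouped samples container
#'
#' @param groups Named list of finite numeric vectors.
#' @param metric Metric name (e.g. "velocity").
#' @param units Units string (e.g. "um/s").
#' @export
grouped_samples <- function(groups, metric = "", units = "") {
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named list")
  if (any(!vapply(groups, function(g) all(is.finite(g)), logical(1))))
    stop("observations must be finite")
  out <- list(groups = groups, metric = metric, units = units)
  class(out) <- "grouped_samples"
  out
}

#' Significance tier from an adjusted p-value
#'
#' Cutoffs 0.05 / 0.01 / 0.001 / 0.0001 map to * / ** / *** / ****; larger
#' p-values are "ns".
#'
#' @param p Adjusted p-value(s).
#' @return Character vector of tiers.
#' @export
significance_tier <- function(p) {
  cut_points <- c(1e-4, 1e-3, 1e-2, 5e-2)
  vapply(p, function(pi) {
    if (pi <= cut_points[1]) "****"
    else if (pi <= cut_points[2]) "***"
    else if (pi <= cut_points[3]) "**"
    else if (pi <= cut_points[4]) "*"
    else "ns"
  }, character(1))
}

#' Pairwise group comparisons with the assay's standard procedures
#'
#' `"kruskal-dunn"` runs a Kruskal-Wallis omnibus test followed by Dunn's
#' pairwise z-tests with tie-corrected rank variance and Bonferroni
#' adjustment (the convention for single-molecule velocity and run-length
#' data). `"welch-dunnettT3"` runs Welch's heteroscedastic ANOVA (plus the
#' Brown-Forsythe F) followed by pairwise Welch t-tests with Sidak
#' adjustment, an approximation to Dunnett's T3 (used for landing-rate and
#' percent-processive data).
#'
#' @param samples A [grouped_samples()] with >= 2 groups of >= 3
#'   observations each.
#' @param method `"kruskal-dunn"` or `"welch-dunnettT3"`.
#' @return List of class `comparison_result`: `method`, `omnibus`
#'   (statistic and p), `pairwise` data.frame (`group1`, `group2`,
#'   `statistic`, `p_raw`, `p_adjusted`, `tier`).
#' @export
compare_groups <- function(samples, method = c("kruskal-dunn", "welch-dunnettT3")) {
  method <- match.arg(method)
  g <- samples$groups
  if (length(g) < 2L) stop("need >= 2 groups")
  n <- vapply(g, length, integer(1))
  if (any(n < 3L)) stop("every group needs >= 3 observations")
  if (all(vapply(g, function(x) stats::var(x) == 0, logical(1))) &&
      length(unique(unlist(g))) == 1L)
    stop("constant data")
  pairs <- utils::combn(names(g), 2)
  if (method == "kruskal-dunn") {
    kw <- stats::kruskal.test(g)
    pw <- dunn_pairwise(g, pairs)
    omni <- list(test = "Kruskal-Wallis", statistic = unname(kw$statistic),
                 p = kw$p.value)
  } else {
    values <- unlist(g, use.names = FALSE)
    labels <- factor(rep(names(g), n))
    welch <- stats::oneway.test(values ~ labels, var.equal = FALSE)
    bf <- brown_forsythe(g)
    pw <- dunnett_t3_pairwise(g, pairs)
    omni <- list(test = "Welch ANOVA (+ Brown-Forsythe)",
                 statistic = unname(welch$statistic), p = welch$p.value,
                 brown_forsythe_statistic = bf$statistic,
                 brown_forsythe_p = bf$p)
  }
  pw$p_adjusted <- pmin(pmax(pw$p_adjusted, pw$p_raw), 1)
  pw$tier <- significance_tier(pw$p_adjusted)
  out <- list(method = method, omnibus = omni, pairwise = pw,
              metric = samples$metric, units = samples$units)
  class(out) <- "comparison_result"
  out
}

# Dunn's z with tie-corrected rank variance; Bonferroni over all pairs.
dunn_pairwise <- function(g, pairs) {
  values <- unlist(g, use.names = FALSE)
  labels <- rep(names(g), vapply(g, length, integer(1)))
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(r, labels, mean)
  n <- tapply(r, labels, length)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    statistic = NA_real_, p_raw = NA_real_)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    sigma <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[a]] + 1 / n[[b]]))
    z <- (mean_rank[[a]] - mean_rank[[b]]) / sigma
    out$statistic[k] <- z
    out$p_raw[k] <- 2 * stats::pnorm(-abs(z))
  }
  out$p_adjusted <- pmin(out$p_raw * ncol(pairs), 1)
  out
}

# Brown-Forsythe (1974) F* for means under heteroscedasticity.
brown_forsythe <- function(g) {
  n <- vapply(g, length, numeric(1))
  m <- vapply(g, mean, numeric(1))
  v <- vapply(g, stats::var, numeric(1))
  N <- sum(n)
  grand <- sum(n * m) / N
  num <- sum(n * (m - grand)^2)
  den <- sum((1 - n / N) * v)
  Fstar <- num / den
  c_i <- (1 - n / N) * v / den
  df2 <- 1 / sum(c_i^2 / (n - 1))
  df1 <- length(g) - 1
  list(statistic = Fstar, df1 = df1, df2 = df2,
       p = stats::pf(Fstar, df1, df2, lower.tail = FALSE))
}

# Pairwise Welch t with Sidak adjustment (Dunnett T3 approximation).
dunnett_t3_pairwise <- function(g, pairs) {
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    statistic = NA_real_, p_raw = NA_real_)
  for (k in seq_len(ncol(pairs))) {
    a <- g[[pairs[1, k]]]; b <- g[[pairs[2, k]]]
    tt <- stats::t.test(a, b, var.equal = FALSE)
    out$statistic[k] <- unname(tt$statistic)
    out$p_raw[k] <- tt$p.value
  }
  out$p_adjusted <- 1 - (1 - out$p_raw)^ncol(pairs)
  out
}

#' Summary table in a figure-legend style
#'
#' @param samples A [grouped_samples()].
#' @param style One of `"median-IQR"`, `"mean-SEM"`, `"mean-SD"`,
#'   `"mean-CI95"`. Quantiles use linear interpolation (type 7).
#' @return data.frame with one row per group: `group`, `n`, `location`,
#'   `spread_low`, `spread_high`, `style`.
#' @export
summarize_metric <- function(samples, style = c("median-IQR", "mean-SEM",
                                                "mean-SD", "mean-CI95")) {
  style <- match.arg(style)
  g <- samples$groups
  if (any(vapply(g, length, integer(1)) == 0L)) stop("empty group")
  rows <- lapply(names(g), function(nm) {
    x <- g[[nm]]; n <- length(x)
    if (style == "median-IQR") {
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      data.frame(group = nm, n = n, location = q[2],
                 spread_low = q[1], spread_high = q[3], style = style)
    } else {
      m <- mean(x); s <- stats::sd(x)
      half <- switch(style,
                     "mean-SEM" = s / sqrt(n),
                     "mean-SD" = s,
                     "mean-CI95" = stats::qt(0.975, n - 1) * s / sqrt(n))
      data.frame(group = nm, n = n, location = m,
                 spread_low = m - half, spread_high = m + half, style = style)
    }
  })
  do.call(rbind, rows)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s on %s%s\n", x$omnibus$test, x$metric,
              if (nzchar(x$units)) paste0(" (", x$units, ")") else ""))
  cat(sprintf("  omnibus statistic %.4g, p = %.3g\n", x$omnibus$statistic, x$omnibus$p))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
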
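# Distribution and statistics layer: number density functions of the total
# LacY concentration, bimodality splitting, heavy-tail summaries, division
# time statistics and chain-vs-population distribution distances.

.get_samples <- function(x, observable = "Y_total_nM") {
  if (is.numeric(x)) return(x)
  if (inherits(x, "lac_population")) x <- x$snapshots
  if (inherits(x, "lac_chain")) x <- x$samples
  if (is.list(x) && !is.null(x$snapshots)) x <- x$snapshots
  if (is.data.frame(x)) {
    if (!observable %in% names(x)) {
      stop("observable '", observable, "' not found")
    }
    return(x[[observable]])
  }
  stop("cannot extract samples from object of class ", class(x)[1])
}

#' Number density function of a population observable
#'
#' Histograms an observable (default total LacY concentration) over all
#' cells of a snapshot, either as raw counts or normalized to unit area so
#' that models with different census sizes can be compared.
#'
#' @param x a `lac_population`, `lac_chain`, snapshot data frame or numeric
#'   vector of samples.
#' @param observable column name (default `"Y_total_nM"`).
#' @param bins number of equal-width bins, or an explicit vector of bin
#'   edges; the default 60 bins span `[0, 1.05 * max]`.
#' @param normalize `"density"` (unit area) or `"counts"`.
#' @return object of class `lac_histogram`: data frame `bin_left`,
#'   `bin_right`, `count`, `density` with the raw samples attached as
#'   `attr(, "samples")`.
#' @export
ndf <- function(x, observable = "Y_total_nM", bins = 60,
                normalize = c("density", "counts")) {
  normalize <- match.arg(normalize)
  s <- .get_samples(x, observable)
  if (!length(s)) stop("empty snapshot")
  if (length(bins) == 1) {
    hi <- max(s) * 1.05
    if (hi <= 0) hi <- 1
    edges <- seq(0, hi, length.out = bins + 1)
    if (min(s) < 0) edges <- seq(min(s), hi, length.out = bins + 1)
  } else {
    edges <- bins
  }
  ct <- graphics::hist(s, breaks = edges, plot = FALSE)
  w <- diff(edges)
  dens <- ct$counts / (sum(ct$counts) * w)
  out <- data.frame(bin_left = utils::head(edges, -1),
                    bin_right = edges[-1],
                    count = ct$counts, density = dens)
  attr(out, "samples") <- s
  attr(out, "normalize") <- normalize
  attr(out, "observable") <- observable
  class(out) <- c("lac_histogram", "data.frame")
  out
}

#' @export
plot.lac_histogram <- function(x, y, ...) {
  mids <- (x$bin_left + x$bin_right) / 2
  h <- if (identical(attr(x, "normalize"), "counts")) x$count else x$density
  graphics::plot(mids, h, type = "s", xlab = attr(x, "observable"),
                 ylab = attr(x, "normalize"), ...)
  invisible(x)
}

#' Split a (possibly bimodal) distribution into subpopulation modes
#'
#' Detects one or two modes in a sample by locating the deepest internal
#' minimum of a kernel-smoothed density (Silverman bandwidth). A valley
#' counts only if the smoothed density there is below `valley_frac` (default
#' 50 percent) of the lower of the two flanking peaks - otherwise the sample
#' is declared unimodal. Per-mode means, standard deviations and weights are
#' computed from the raw samples on each side of the valley.
#'
#' @param x samples (or an object accepted by [ndf()]).
#' @param observable column to analyse when `x` is a data frame.
#' @param valley_frac valley-depth acceptance threshold in (0, 1).
#' @return data frame (class `lac_modes`) with one row per mode: `mode`,
#'   `mean`, `sd`, `weight`, `n`; the split point (or NA) is in
#'   `attr(, "split_at")`.
#' @export
split_modes <- function(x, observable = "Y_total_nM", valley_frac = 0.5) {
  if (inherits(x, "lac_histogram")) x <- attr(x, "samples")
  s <- .get_samples(x, observable)
  if (!length(s)) stop("empty sample")
  if (length(unique(s)) < 3 || stats::sd(s) == 0) {
    out <- data.frame(mode = 1L, mean = mean(s), sd = stats::sd(s),
                      weight = 1, n = length(s))
    attr(out, "split_at") <- NA_real_
    class(out) <- c("lac_modes", "data.frame")
    return(out)
  }
  d <- stats::density(s, bw = "nrd0")
  yy <- d$y; xx <- d$x
  n <- length(yy)
  is_min <- c(FALSE, yy[2:(n - 1)] < yy[1:(n - 2)] &
                     yy[2:(n - 1)] <= yy[3:n], FALSE)
  split_at <- NA_real_
  if (any(is_min)) {
    best <- NA_real_; best_score <- Inf
    for (i in which(is_min)) {
      pl <- max(yy[1:i]); pr <- max(yy[i:n])
      score <- yy[i] / min(pl, pr)
      if (score < best_score) { best_score <- score; best <- xx[i] }
    }
    if (best_score < valley_frac &&
        sum(s <= best) > 0 && sum(s > best) > 0) {
      split_at <- best
    }
  }
  if (is.na(split_at)) {
    out <- data.frame(mode = 1L, mean = mean(s), sd = stats::sd(s),
                      weight = 1, n = length(s))
  } else {
    lo <- s[s <= split_at]; hi <- s[s > split_at]
    out <- data.frame(
      mode = c(1L, 2L),
      mean = c(mean(lo), mean(hi)),
      sd = c(stats::sd(lo), stats::sd(hi)),
      weight = c(length(lo), length(hi)) / length(s),
      n = c(length(lo), length(hi)))
  }
  attr(out, "split_at") <- split_at
  class(out) <- c("lac_modes", "data.frame")
  out
}

#' Heavy-tail and shape statistics of a sample
#'
#' Moment and quantile summaries used to quantify heavy-tailedness of
#' phenotypic distributions: sample skewness, excess kurtosis and the
#' fraction of mass above mean + 3 standard deviations.
#'
#' @param x samples (>= 10) or an object accepted by [ndf()].
#' @param observable column to analyse when `x` is a data frame.
#' @return list `skewness`, `excess_kurtosis`, `tail_mass_3sd`,
#'   `degenerate` (TRUE for a zero-variance sample, in which case the
#'   moments are NA).
#' @export
tail_and_shape_stats <- function(x, observable = "Y_total_nM") {
  s <- .get_samples(x, observable)
  if (length(s) < 10) stop("need at least 10 samples")
  m <- mean(s); sdev <- stats::sd(s)
  if (sdev == 0) {
    return(list(skewness = NA_real_, excess_kurtosis = NA_real_,
                tail_mass_3sd = 0, degenerate = TRUE))
  }
  z <- (s - m) / sdev
  list(skewness = mean(z^3),
       excess_kurtosis = mean(z^4) - 3,
       tail_mass_3sd = mean(s > m + 3 * sdev),
       degenerate = FALSE)
}

#' Division-time distribution
#'
#' Histogram, mean and coefficient of variation of mother-birth-to-division
#' intervals.
#'
#' @param x a `lac_chain` (interdivision intervals along the lineage), a
#'   `lac_population` (per-cell birth-to-division intervals from the event
#'   log) or a numeric vector of intervals (min).
#' @param bins number of bins.
#' @return list `histogram` (a `lac_histogram`), `mean`, `cv`, `n`.
#' @export
division_time_histogram <- function(x, bins = 40) {
  iv <- if (is.numeric(x)) {
    x
  } else if (inherits(x, "lac_chain")) {
    dt <- x$division_times
    if (length(dt) < 1) stop("no division recorded")
    diff(c(x$samples$time_min[1], dt))
  } else if (inherits(x, "lac_population")) {
    with(x$events, division_min - birth_min)
  } else {
    stop("unsupported input")
  }
  if (!length(iv)) stop("no division intervals")
  h <- ndf(iv, bins = bins)
  list(histogram = h, mean = mean(iv),
       cv = stats::sd(iv) / mean(iv), n = length(iv))
}

#' Kolmogorov-Smirnov distance between two sample sets
#'
#' Two-sample Kolmogorov-Smirnov statistic (sup-distance between empirical
#' CDFs, in [0, 1]) of an observable, used to compare the stationary cell
#' chain distribution with the population number density function.
#' Ties (e.g. many cells at zero LacY) are handled exactly by evaluating
#' both ECDFs on the pooled support.
#'
#' @param a,b sample vectors or objects accepted by [ndf()].
#' @param observable column to compare when inputs are data frames.
#' @return KS statistic in [0, 1].
#' @export
distribution_distance <- function(a, b, observable = "Y_total_nM") {
  sa <- .get_samples(a, observable)
  sb <- .get_samples(b, observable)
  if (!length(sa) || !length(sb)) stop("empty sample set")
  pts <- sort(unique(c(sa, sb)))
  Fa <- stats::ecdf(sa)(pts)
  Fb <- stats::ecdf(sb)(pts)
  max(abs(Fa - Fb))
}
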
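#' Rule-of-thumb (nrd0) kernel bandwidth
#'
#' Silverman's rule of thumb as used for gene-expression density estimation:
#' `0.9 * min(sd, IQR/1.34) * n^(-1/5)`, with the reference fallback chain when
#' the spread estimate is zero (substitute `max(sd, IQR/1.34)`, then `|x[1]|`,
#' then 1). Deliberately conservative: it oversmooths relative to plug-in
#' selectors such as Sheather-Jones, so only large density fluctuations
#' survive into peak calling.
#'
#' @param values Numeric vector of at least two finite observations.
#' @return A single positive bandwidth.
#' @examples
#' nrd0_bandwidth(c(1, 2, 3, 4, 5))
#' @export
nrd0_bandwidth <- function(values) {
  if (!is.numeric(values) || length(values) < 2) {
    abort("`values` must be a numeric vector with at least 2 observations.")
  }
  if (!all(is.finite(values))) {
    abort("`values` must be finite.")
  }
  n <- length(values)
  spread <- min(sd(values), IQR(values) / 1.34)
  if (spread == 0) spread <- max(sd(values), IQR(values) / 1.34)
  if (spread == 0) spread <- abs(values[1L])
  if (spread == 0) spread <- 1
  0.9 * spread * n^(-1 / 5)
}

#' Kernel density estimate of an expression distribution
#'
#' Gaussian kernel density evaluated on 512 equally spaced points spanning
#' `[min(values) - 3*bw, max(values) + 3*bw]` (the classic R density grid the
#' detector is built around).
#'
#' @param values Numeric vector (>= 2 finite observations).
#' @param bandwidth Kernel bandwidth; defaults to [nrd0_bandwidth()].
#' @return A `density_curve` tibble with columns `x` (grid) and `y` (density),
#'   and attributes `bandwidth` and `n_obs`.
#' @examples
#' curve <- estimate_density(rnorm(200))
#' @export
estimate_density <- function(values, bandwidth = NULL) {
  if (!is.numeric(values) || length(values) < 2 || !all(is.finite(values))) {
    abort("`values` must be a finite numeric vector with at least 2 observations.")
  }
  bandwidth <- bandwidth %||% nrd0_bandwidth(values)
  if (!is.numeric(bandwidth) || length(bandwidth) != 1 || bandwidth <= 0) {
    abort("`bandwidth` must be a single positive number.")
  }
  d <- density(values, bw = bandwidth, kernel = "gaussian", n = 512L, cut = 3)
  out <- tibble(x = d$x, y = d$y)
  attr(out, "bandwidth") <- bandwidth
  attr(out, "n_obs") <- length(values)
  class(out) <- c("density_curve", class(out))
  out
}

#' First derivative of a density curve, optionally spline-smoothed
#'
#' The slope is the central finite difference on the grid (one-sided at the
#' ends). With `smoothing = TRUE` a cubic smoothing spline is fit to the slope
#' values, the penalty chosen by generalized cross-validation, and evaluated
#' back on the same grid; this damps the small derivative wiggles that would
#' otherwise spawn spurious sign changes in the upper tail.
#'
#' @param curve A `density_curve` from [estimate_density()].
#' @param smoothing Logical; apply GCV spline smoothing to the slope.
#' @param spar Optional numeric in (0, 1] overriding the GCV-chosen smoothing
#'   parameter.
#' @return A `derivative_curve` tibble with columns `x` and `dydx` and
#'   attribute `smoothed`.
#' @export
density_derivative <- function(curve, smoothing = TRUE, spar = NULL) {
  stopifnot(is.data.frame(curve), all(c("x", "y") %in% names(curve)))
  x <- curve$x
  y <- curve$y
  n <- length(x)
  dydx <- numeric(n)
  dydx[1L] <- (y[2L] - y[1L]) / (x[2L] - x[1L])
  dydx[n] <- (y[n] - y[n - 1L]) / (x[n] - x[n - 1L])
  mid <- 2:(n - 1L)
  dydx[mid] <- (y[mid + 1L] - y[mid - 1L]) / (x[mid + 1L] - x[mid - 1L])
  if (isTRUE(smoothing)) {
    if (!is.null(spar) && (!is.numeric(spar) || spar <= 0 || spar > 1)) {
      abort("`spar` must be a number in (0, 1].")
    }
    fit <- if (is.null(spar)) {
      smooth.spline(x, dydx, cv = FALSE)
    } else {
      smooth.spline(x, dydx, spar = spar)
    }
    dydx <- predict(fit, x)$y
  }
  out <- tibble(x = x, dydx = dydx)
  attr(out, "smoothed") <- isTRUE(smoothing)
  class(out) <- c("derivative_curve", class(out))
  out
}

# Indices where the derivative changes sign. A run of exact zeros between two
# opposite signs takes the midpoint of the run; endpoints are never candidates.
derivative_sign_changes <- function(dydx) {
  s <- sign(dydx)
  nz <- which(s != 0)
  out <- list(peak = integer(), valley = integer())
  if (length(nz) < 2) {
    return(out)
  }
  for (j in seq_len(length(nz) - 1L)) {
    i1 <- nz[j]
    i2 <- nz[j + 1L]
    if (s[i1] == s[i2]) next
    # crossing somewhere in (i1, i2]; zeros in between take the midpoint
    idx <- if (i2 - i1 > 1L) as.integer(round((i1 + i2) / 2)) else i1
    if (s[i1] > 0) out$peak <- c(out$peak, idx) else out$valley <- c(out$valley, idx)
  }
  out
}

#' Call peaks and valleys on a density curve
#'
#' Candidate peaks sit where the (smoothed) density derivative flips from
#' positive to negative, valleys where it flips the other way. Two height
#' rules then prune the candidates, both expressed as fractions of the maximum
#' density value:
#'
#' * `threshold_down` (default 0.20): candidate peaks lower than this fraction
#'   of the maximum density are discarded outright — they are typically ripples
#'   in the sparse upper tail of the expression distribution.
#' * `threshold_up` (default 0.10): after pruning, any adjacent peak--valley
#'   pair whose height gap is below this fraction is treated as one peak; the
#'   taller of the two flanking peaks is kept (ties keep the leftmost).
#'
#' Grid endpoints are never counted as peaks, retained peaks and valleys
#' alternate along the axis, and valleys are the density minima between
#' consecutive retained peaks.
#'
#' @param curve A `density_curve` from [estimate_density()].
#' @param deriv Optional matching `derivative_curve`; computed (with
#'   `smoothing`) when omitted.
#' @param threshold_up,threshold_down Fractions in \[0, 1\] of the maximum
#'   density value (defaults 0.10 and 0.20).
#' @param smoothing Passed to [density_derivative()] when `deriv` is omitted.
#' @return A `peak_set` object: list with tibbles `peaks` and `valleys`
#'   (columns `location`, `height`, `index`) and the count `n_peaks`.
#' @examples
#' x <- c(rnorm(300), rnorm(300, 6))
#' detect_peaks(estimate_density(x))
#' @export
detect_peaks <- function(curve, deriv = NULL, threshold_up = 0.10,
                         threshold_down = 0.20, smoothing = TRUE) {
  stopifnot(is.data.frame(curve), all(c("x", "y") %in% names(curve)))
  if (is.null(deriv)) deriv <- density_derivative(curve, smoothing = smoothing)
  if (!isTRUE(all.equal(curve$x, deriv$x))) {
    abort("`curve` and `deriv` must share the same grid.")
  }
  if (threshold_up < 0 || threshold_up > 1 || threshold_down < 0 || threshold_down > 1) {
    abort("thresholds must lie in [0, 1].")
  }
  x <- curve$x
  y <- curve$y
  n <- length(x)
  max_y <- max(y)

  cand <- derivative_sign_changes(deriv$dydx)
  pk <- setdiff(cand$peak, c(1L, n))
  # Threshold Down: drop low candidate peaks
  pk <- pk[y[pk] >= threshold_down * max_y]
  pk <- sort(pk)

  # valleys = density minimum between consecutive surviving peaks
  valley_between <- function(i1, i2) {
    rng <- (i1 + 1L):(i2 - 1L)
    if (length(rng) == 0L) rng <- i1
    rng[which.min(y[rng])]
  }
  vl <- integer(0)
  if (length(pk) >= 2) {
    vl <- vapply(seq_len(length(pk) - 1L), function(j) {
      valley_between(pk[j], pk[j + 1L])
    }, integer(1))
  }

  # Threshold Up: merge adjacent peak-valley pairs with a small height gap
  repeat {
    if (length(pk) < 2) break
    gaps <- numeric(length(vl))
    drop_peak <- integer(length(vl))
    for (j in seq_along(vl)) {
      g1 <- y[pk[j]] - y[vl[j]]
      g2 <- y[pk[j + 1L]] - y[vl[j]]
      gaps[j] <- min(g1, g2)
      # shorter flanking peak is absorbed; ties keep the leftmost peak
      drop_peak[j] <- if (y[pk[j]] >= y[pk[j + 1L]]) j + 1L else j
    }
    shallow <- which(gaps < threshold_up * max_y)
    if (length(shallow) == 0L) break
    j <- shallow[which.min(gaps[shallow])]
    pk <- pk[-drop_peak[j]]
    vl <- integer(0)
    if (length(pk) >= 2) {
      vl <- vapply(seq_len(length(pk) - 1L), function(j2) {
        valley_between(pk[j2], pk[j2 + 1L])
      }, integer(1))
    }
  }

  out <- structure(
    list(
      peaks = tibble(location = x[pk], height = y[pk], index = pk),
      valleys = tibble(location = x[vl], height = y[vl], index = vl),
      n_peaks = length(pk),
      threshold_up = threshold_up,
      threshold_down = threshold_down,
      curve = curve
    ),
    class = "peak_set"
  )
  out
}

#' @export
print.peak_set <- function(x, ...) {
  cat("<peak_set> ", x$n_peaks, " peak(s), ",
    nrow(x$valleys), " valley(s)\n",
    sep = ""
  )
  if (x$n_peaks > 0) {
    cat("  peak locations: ", paste(signif(x$peaks$location, 4), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @describeIn detect_peaks Tidy the retained peaks and valleys into one tibble
#'   with a `type` column.
#' @param x A `peak_set`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.peak_set <- function(x, ...) {
  dplyr::arrange(
    dplyr::bind_rows(
      dplyr::mutate(x$peaks, type = "peak"),
      dplyr::mutate(x$valleys, type = "valley")
    ),
    .data$location
  )
}

#' @describeIn detect_peaks One-row summary (peak count and thresholds).
#' @exportS3Method generics::glance
glance.peak_set <- function(x, ...) {
  tibble(
    n_peaks = x$n_peaks,
    n_valleys = nrow(x$valleys),
    threshold_up = x$threshold_up,
    threshold_down = x$threshold_down,
    bandwidth = attr(x$curve, "bandwidth") %||% NA_real_
  )
}
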
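#' Map SVM margins to calibrated probabilities
#'
#' Fits a monotone non-decreasing map from signed margin distances to
#' probabilities in \[0, 1\], so that among records mapped to probability p a
#' fraction of about p is truly positive. Two interchangeable calibrators are
#' provided behind the same interface:
#'
#' * `"isotonic"` (default): isotonic regression of the 0/1 labels on the
#'   margins (pool-adjacent-violators via [stats::isoreg()]), clipped to
#'   `[eps, 1 - eps]` and linearly interpolated between knots; constant
#'   beyond the fitted range.
#' * `"sigmoid"`: a Platt-style sigmoid `1 / (1 + exp(A m + B))` fitted by
#'   maximum likelihood with smoothed targets, which keeps the fit finite
#'   even under perfect separation. If the fitted slope is not monotone
#'   non-decreasing (pathological anti-correlated input) the map falls back
#'   to the constant prevalence.
#'
#' Calibration must be fitted on margins from data the margin model was not
#' trained on (the tagger uses an internal held-out split for this).
#'
#' @param margins numeric vector of signed margins (finite).
#' @param labels logical (or 0/1) labels; both classes required.
#' @param method `"isotonic"` or `"sigmoid"`.
#' @param eps clipping bound keeping probabilities off exact 0/1.
#' @return object of class `"calibration_map"`.
#' @export
fit_calibration <- function(margins, labels,
                            method = c("isotonic", "sigmoid"), eps = 1e-4) {
  method <- match.arg(method)
  y <- as.numeric(labels)
  stop_if_not(all(y %in% c(0, 1)), "labels must be logical or 0/1")
  stop_if_not(length(margins) == length(y), "margins and labels differ in length")
  stop_if_not(all(is.finite(margins)), "margins must be finite")
  stop_if_not(length(unique(y)) == 2, "both classes must be present")
  clip <- function(p) pmin(pmax(p, eps), 1 - eps)
  if (method == "isotonic") {
    ord <- order(margins, y)
    iso <- stats::isoreg(margins[ord], y[ord])
    fitted <- iso$yf
    xs <- margins[ord]
    # collapse tied margins to one knot (group means of a monotone sequence
    # stay monotone across groups)
    knot_y <- as.numeric(tapply(fitted, match(xs, unique(xs)), mean))
    knot_x <- unique(xs)
    structure(list(method = "isotonic", eps = eps,
                   knots_x = knot_x, knots_y = clip(knot_y)),
              class = "calibration_map")
  } else {
    # Platt's smoothed targets guard against infinite coefficients when the
    # margins separate the classes perfectly
    n_pos <- sum(y == 1); n_neg <- sum(y == 0)
    t_pos <- (n_pos + 1) / (n_pos + 2); t_neg <- 1 / (n_neg + 2)
    tt <- ifelse(y == 1, t_pos, t_neg)
    nll <- function(par) {
      z <- par[1] * margins + par[2]
      # -sum(t*log(p) + (1-t)*log(1-p)) with p = 1/(1+exp(z)), stable form
      sum(pmax(z, 0) + log1p(exp(-abs(z))) - (1 - tt) * z)
    }
    fit <- stats::optim(c(A = 0, B = log((n_neg + 1) / (n_pos + 1))), nll,
                        method = "BFGS", control = list(maxit = 500))
    A <- fit$par[1]; B <- fit$par[2]
    if (A > 0) {  # non-monotone direction: fall back to constant prevalence
      A <- 0; B <- -stats::qlogis(clip(mean(y)))
    }
    structure(list(method = "sigmoid", eps = eps, A = unname(A), B = unname(B)),
              class = "calibration_map")
  }
}

#' Apply a calibration map
#'
#' @param map a [fit_calibration()] result.
#' @param margin numeric vector of signed margins (any real values).
#' @return probabilities in \[0, 1\], non-decreasing in `margin`.
#' @export
calibrate <- function(map, margin) {
  stop_if_not(inherits(map, "calibration_map"), "not a calibration_map")
  if (length(margin) == 0) return(numeric(0))
  if (map$method == "isotonic") {
    if (length(map$knots_x) == 1) return(rep(map$knots_y, length(margin)))
    stats::approx(map$knots_x, map$knots_y, xout = margin, rule = 2)$y
  } else {
    pmin(pmax(stats::plogis(-(map$A * margin + map$B)), map$eps), 1 - map$eps)
  }
}

#' @export
print.calibration_map <- function(x, ...) {
  if (x$method == "isotonic") {
    cat(sprintf("<calibration_map> isotonic, %d knots on [%.3g, %.3g]\n",
                length(x$knots_x), min(x$knots_x), max(x$knots_x)))
  } else {
    cat(sprintf("<calibration_map> sigmoid, A=%.4g B=%.4g\n", x$A, x$B))
  }
  invisible(x)
}
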
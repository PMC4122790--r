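#' Automatic histogram thresholding
#'
#' Binarizes an 8-bit image (typically a gradient-magnitude image) with one
#' of six classical histogram methods.  The default, IsoData, returns the
#' threshold `t` satisfying the intermeans fixed point
#' `t = floor((mean(v <= t) + mean(v > t)) / 2)`, initialized at the midpoint
#' of the occupied intensity range and iterated to convergence.  The output
#' is `value > t`.
#'
#' @param img numeric matrix with integer values in 0..255
#' @param method one of `"isodata"`, `"otsu"`, `"mean"`, `"triangle"`,
#'   `"li"`, `"yen"`
#' @return logical matrix `img > t`, with the chosen threshold attached as
#'   attribute `"threshold"`
#' @seealso [threshold_gallery()] to compare all methods on one image
#' @export
auto_threshold <- function(img, method = c("isodata", "otsu", "mean",
                                           "triangle", "li", "yen")) {
  method <- match.arg(method)
  v <- as.vector(img)
  if (anyNA(v)) stop("image contains NA")
  if (min(v) == max(v))
    stop("degenerate-histogram: all pixels have the same value")
  t <- switch(method,
    isodata = threshold_isodata(v),
    otsu = threshold_otsu(v),
    mean = floor(mean(v)),
    triangle = threshold_triangle(v),
    li = threshold_li(v),
    yen = threshold_yen(v))
  structure(img > t, dim = dim(img), threshold = t)
}

#' Supported auto-threshold method names
#' @return character vector, IsoData first
#' @export
threshold_methods <- function() c("isodata", "otsu", "mean", "triangle",
                                  "li", "yen")

#' Apply every auto-threshold method to one image
#'
#' Produces one binary image per supported method so the user can compare
#' them side by side before picking the method used to build edge maps.
#' A method that fails (degenerate histogram) contributes its error message
#' instead of aborting the gallery.
#'
#' @inheritParams auto_threshold
#' @return named list in [threshold_methods()] order; each element is either
#'   a logical matrix or a condition object
#' @export
threshold_gallery <- function(img) {
  out <- lapply(threshold_methods(), function(m)
    tryCatch(auto_threshold(img, m), error = function(e) e))
  names(out) <- threshold_methods()
  out
}

threshold_isodata <- function(v) {
  t <- floor((min(v) + max(v)) / 2)
  seen <- integer(0)
  repeat {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(hi) == 0L) { t <- t - 1L; next }
    if (length(lo) == 0L) { t <- t + 1L; next }
    t2 <- floor((mean(lo) + mean(hi)) / 2)
    if (t2 == t) return(t)
    if (t2 %in% seen) return(t2)   # limit cycle: accept current iterate
    seen <- c(seen, t)
    t <- t2
  }
}

threshold_otsu <- function(v) {
  h <- tabulate(as.integer(v) + 1L, 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- -Inf
  which.max(sb) - 1L   # class 0 is <= t
}

threshold_triangle <- function(v) {
  h <- tabulate(as.integer(v) + 1L, 256L)
  peak <- which.max(h)
  nz <- which(h > 0)
  lo <- nz[1]; hi <- nz[length(nz)]
  # use the longer tail from the peak
  if ((peak - lo) >= (hi - peak)) { a <- lo; b <- peak; flip <- TRUE }
  else { a <- peak; b <- hi; flip <- FALSE }
  if (a == b) return(a - 1L)
  xs <- a:b
  # distance from (x, h[x]) to the line joining (peak, h[peak]) and the tail end
  x1 <- if (flip) b else a; y1 <- h[x1]
  x2 <- if (flip) a else b; y2 <- h[x2]
  d <- abs((y2 - y1) * xs - (x2 - x1) * h[xs] + x2 * y1 - y2 * x1)
  best <- xs[which.max(d)]
  best - 1L
}

threshold_li <- function(v) {
  # Li & Tam iterative minimum cross-entropy; intensities offset by +1 so the
  # logarithms are defined for images containing 0.
  x <- as.numeric(v) + 1
  t <- mean(x)
  repeat {
    mb <- mean(x[x <= t]); mf <- mean(x[x > t])
    if (!is.finite(mb) || !is.finite(mf)) break
    t2 <- (mb - mf) / (log(mb) - log(mf))
    if (!is.finite(t2) || abs(t2 - t) < 0.5) { t <- t2; break }
    t <- t2
  }
  as.integer(floor(t - 1))
}

threshold_yen <- function(v) {
  h <- tabulate(as.integer(v) + 1L, 256L)
  p <- h / sum(h)
  P1 <- cumsum(p)
  P1sq <- cumsum(p^2)
  P2sq <- sum(p^2) - P1sq
  crit <- -log(pmax(P1sq * P2sq, .Machine$double.xmin)) +
    2 * log(pmax(P1 * (1 - P1), .Machine$double.xmin))
  crit[P1 <= 0 | P1 >= 1] <- -Inf
  which.max(crit) - 1L
}
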
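# VORS ecosystem health: vitality (normalized NPP), organization (EO from
# landscape metrics), resilience (land-cover resistance/recovery
# coefficients), an entropy-weighted ecosystem service index, and their
# geometric mean EHI.

#' Resilience and resistance coefficients per land-cover class
#'
#' @return Tibble with `class`, `resistance`, `resilience`.
#' @export
resilience_coefficients <- function() {
  tibble::tibble(
    class = c("farmland", "forest", "grassland", "water", "construction",
              "desert"),
    resistance = c(0.6, 1.0, 0.6, 0.8, 0.3, 0.2),
    resilience = c(0.4, 0.9, 0.7, 0.8, 0.2, 0.1)
  )
}

#' Ecosystem vitality EV
#'
#' Unit-mean NPP, min-max normalized across every row passed in (pool all
#' years first so the scale is temporally comparable).
#'
#' @param npp_units Tibble with a `value` column of unit-mean NPP (from
#'   [aggregate_to_units()]), or a numeric vector.
#' @return Numeric vector of EV in [0, 1].
#' @export
vitality <- function(npp_units) {
  x <- if (is.data.frame(npp_units)) npp_units$value else npp_units
  r <- range(x, na.rm = TRUE)
  if (r[2] - r[1] <= 0)
    stop("NPP is constant across units; vitality is undefined",
         call. = FALSE)
  minmax_norm(x)
}

#' Ecosystem resilience ER
#'
#' Per unit, `sum_i A_i * (0.4 * C_resistant_i + 0.6 * C_resilient_i)`
#' with `A_i` the within-unit area proportion of class i, so ER is
#' scale-free in [0.14, 0.94] under the default coefficients.
#'
#' @param props Tibble from [unit_class_proportions()] (one proportion
#'   column per class present).
#' @param coeffs Coefficient table as [resilience_coefficients()].
#' @return Numeric vector of ER per unit.
#' @export
resilience <- function(props, coeffs = resilience_coefficients()) {
  cls <- intersect(names(props),
                   c("farmland", "forest", "grassland", "water",
                     "construction", "desert"))
  miss <- setdiff(cls, coeffs$class)
  if (length(miss))
    stop("no coefficients for class(es): ", paste(miss, collapse = ", "),
         call. = FALSE)
  er <- rep(0, nrow(props))
  for (cl in cls) {
    row <- coeffs[coeffs$class == cl, ]
    er <- er + props[[cl]] * (0.4 * row$resistance + 0.6 * row$resilience)
  }
  er
}

#' Entropy weights for a units x indicators matrix
#'
#' Indicators should already be min-max normalized to [0, 1]. Zeros are
#' shifted by `eps` before forming column shares; weights are
#' `(1 - e_j) / sum(1 - e_k)` with `e_j` the normalized Shannon entropy of
#' column j. Constant columns carry (numerically) zero information and so
#' get (numerically) zero weight; if every column is constant the weights
#' fall back to equal with a warning.
#'
#' @param X Numeric matrix or data frame (n >= 2 rows).
#' @param eps Zero shift.
#' @return Named numeric weights summing to 1.
#' @export
entropy_weights <- function(X, eps = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 2)
  Xs <- pmax(X, eps)
  p <- sweep(Xs, 2, colSums(Xs), "/")
  e <- -colSums(p * log(p)) / log(n)
  d <- 1 - e
  if (sum(d) <= 1e-12) {
    warning("all indicators are constant; falling back to equal weights",
            call. = FALSE)
    w <- rep(1 / ncol(X), ncol(X))
  } else {
    w <- d / sum(d)
  }
  names(w) <- colnames(X)
  w
}

#' Ecosystem service index ESI
#'
#' Weighted sum of the (already normalized, pooled across years) service
#' indicators.
#'
#' @param P Matrix/data frame of normalized service values in [0, 1].
#' @param w Weights summing to 1 (default: [entropy_weights()] of `P`).
#' @return Numeric vector of ESI in [0, 1].
#' @export
service_index <- function(P, w = entropy_weights(P)) {
  P <- as.matrix(P)
  stopifnot(ncol(P) == length(w))
  as.numeric(P %*% w)
}

#' Ecosystem health index EHI
#'
#' Geometric mean of the four components:
#' `EHI = (EV * EO * ER * ESI)^(1/4)`.
#'
#' @param ev,eo,er,esi Component vectors, all in [0, 1].
#' @return Numeric vector of EHI in [0, 1].
#' @export
ehi <- function(ev, eo, er, esi) {
  comp <- cbind(ev, eo, er, esi)
  if (any(comp < -1e-12 | comp > 1 + 1e-12, na.rm = TRUE))
    stop("EHI components must lie in [0, 1]", call. = FALSE)
  comp <- pmin(pmax(comp, 0), 1)
  as.numeric((comp[, 1] * comp[, 2] * comp[, 3] * comp[, 4])^(1 / 4))
}

#' Classify an index layer into five ordered levels
#'
#' Levels `very poor` < `poor` < `moderate` < `good` < `excellent`, by
#' equal intervals on [0, 1] (default) or sample quantiles. Area shares
#' are percentages of units and sum to 100.
#'
#' @param x Numeric index values in [0, 1].
#' @param scheme `"equal_interval"` or `"quantile"`.
#' @param k Number of classes (default 5).
#' @param labels Level labels (length `k`).
#' @return List: `level` (ordered factor per unit) and `shares` (named
#'   percentage vector).
#' @export
classify_levels <- function(x, scheme = c("equal_interval", "quantile"),
                            k = 5,
                            labels = c("very poor", "poor", "moderate",
                                       "good", "excellent")) {
  scheme <- match.arg(scheme)
  stopifnot(k >= 2, length(labels) == k)
  if (length(unique(x)) < k)
    warning("fewer distinct values than classes; classification is ",
            "degenerate", call. = FALSE)
  br <- if (scheme == "equal_interval") {
    (0:k) / k  # exact binary representation of the usual 0.2 steps
  } else {
    unique(quantile(x, probs = seq(0, 1, length.out = k + 1), names = FALSE))
  }
  if (length(br) < 3) br <- c(br[1] - 1e-9, br)
  lev <- cut(x, breaks = br, labels = labels[seq_len(length(br) - 1)],
             include.lowest = TRUE, right = FALSE, ordered_result = TRUE)
  # right = FALSE gives [a, b) bands; include.lowest closes the top band
  lev[x >= br[length(br)]] <- labels[length(br) - 1]
  shares <- 100 * as.numeric(table(lev)) / length(x)
  names(shares) <- levels(lev)
  list(level = lev, shares = shares)
}
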
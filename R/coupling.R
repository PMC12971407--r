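# Coupling coordination degree model (C, T, D with the five-level
# classification) and the z-score four-quadrant zoning of EHI x HAI.

#' Coupling degree C
#'
#' `C = 2 * sqrt(ehi * hai) / (ehi + hai)`; symmetric, in [0, 1], equal to
#' 1 iff the two indices are equal and positive. Both zero is defined as
#' C = 0.
#'
#' @param ehi,hai Index vectors in [0, 1].
#' @return Numeric vector C.
#' @export
coupling_degree <- function(ehi, hai) {
  stopifnot(all(ehi >= 0 & ehi <= 1, na.rm = TRUE),
            all(hai >= 0 & hai <= 1, na.rm = TRUE))
  s <- ehi + hai
  out <- ifelse(s > 0, 2 * sqrt(ehi * hai) / s, 0)
  as.numeric(out)
}

#' Coordination index T
#'
#' Additive (default): `T = alpha * ehi + beta * hai`. The multiplicative
#' form `T = alpha * ehi * beta * hai` is also available for comparison;
#' with alpha = beta = 0.5 it caps T at a quarter of the product and
#' drives D far below the usual coordination bands, so the additive
#' convention is the default.
#'
#' @param ehi,hai Index vectors in [0, 1].
#' @param alpha,beta Subsystem weights, `alpha + beta = 1`.
#' @param mode `"additive"` or `"multiplicative"`.
#' @return Numeric vector T with attribute `mode`.
#' @export
coordination_index <- function(ehi, hai, alpha = 0.5, beta = 0.5,
                               mode = c("additive", "multiplicative")) {
  mode <- match.arg(mode)
  if (abs(alpha + beta - 1) > 1e-9)
    stop("alpha + beta must equal 1", call. = FALSE)
  t <- if (mode == "additive") alpha * ehi + beta * hai
       else alpha * ehi * beta * hai
  attr(t, "mode") <- mode
  t
}

#' Coupling coordination degree D
#'
#' `D = sqrt(C * T)`, in [0, 1].
#'
#' @param C,T Vectors in [0, 1].
#' @return Numeric vector D.
#' @export
ccd <- function(C, T) {
  stopifnot(all(C >= 0 & C <= 1 + 1e-12, na.rm = TRUE),
            all(T >= -1e-12 & T <= 1 + 1e-12, na.rm = TRUE))
  sqrt(pmax(C, 0) * pmax(as.numeric(T), 0))
}

#' Five-level coupling coordination classification
#'
#' Half-open bands with the top band closed: severe dissonance [0, 0.2),
#' mild dissonance [0.2, 0.4), near-dissonance [0.4, 0.6), mild
#' coordination [0.6, 0.8), high coordination [0.8, 1].
#'
#' @param D Coupling coordination degree vector.
#' @return Ordered factor of level labels.
#' @export
classify_ccd <- function(D) {
  labs <- c("severe dissonance", "mild dissonance", "near-dissonance",
            "mild coordination", "high coordination")
  cut(D, breaks = c(0, 0.2, 0.4, 0.6, 0.8, 1), labels = labs,
      include.lowest = TRUE, right = FALSE, ordered_result = TRUE)
}

#' Four-quadrant zoning of EHI x HAI
#'
#' Both indices are z-scored; the (standardized) means separate high from
#' low, with z >= 0 counting as high. Quadrant I (high EHI, high HAI):
#' coordinated development; II (low EHI, high HAI): ecological
#' management; III (low, low): risk prevention; IV (high EHI, low HAI):
#' potential conservation.
#'
#' @param ehi,hai Index vectors (non-degenerate).
#' @param threshold `"zscore_zero"` (default) or `"mean"` — identical
#'   partitions; the z-score form also returns the standardized values.
#' @return Tibble `ehi_z`, `hai_z`, `quadrant` (factor I-IV), `zone`.
#' @export
quadrant_assign <- function(ehi, hai,
                            threshold = c("zscore_zero", "mean")) {
  threshold <- match.arg(threshold)
  if (sd(ehi) <= 0 || sd(hai) <= 0)
    stop("zero variance: quadrant assignment is undefined", call. = FALSE)
  ez <- (ehi - mean(ehi)) / sd(ehi)
  hz <- (hai - mean(hai)) / sd(hai)
  q <- ifelse(ez >= 0 & hz >= 0, "I",
       ifelse(ez < 0 & hz >= 0, "II",
       ifelse(ez < 0 & hz < 0, "III", "IV")))
  zones <- c(I = "coordinated development",
             II = "ecological management",
             III = "risk prevention",
             IV = "potential conservation")
  tibble::tibble(ehi_z = ez, hai_z = hz,
                 quadrant = factor(q, levels = c("I", "II", "III", "IV")),
                 zone = unname(zones[q]))
}

#' Per-quadrant area shares and mean coupling coordination
#'
#' @param quadrants Factor/character of quadrant labels per unit (or the
#'   tibble from [quadrant_assign()]).
#' @param D Coupling coordination degree per unit.
#' @param year Optional year label per unit; summaries are per year and,
#'   when more than one year is present, first-to-last share changes are
#'   attached as an attribute `share_change`.
#' @return Tibble `year`, `quadrant`, `n`, `share` (%), `mean_d`.
#' @export
zone_summary <- function(quadrants, D, year = NULL) {
  if (is.data.frame(quadrants)) quadrants <- quadrants$quadrant
  q <- factor(quadrants, levels = c("I", "II", "III", "IV"))
  if (is.null(year)) year <- rep(1L, length(q))
  df <- tibble::tibble(year = year, quadrant = q, d = D)
  out <- df |>
    dplyr::group_by(year, quadrant, .drop = FALSE) |>
    dplyr::summarise(n = dplyr::n(), mean_d = mean(d), .groups = "drop_last") |>
    dplyr::mutate(share = 100 * n / sum(n)) |>
    dplyr::ungroup() |>
    dplyr::select(year, quadrant, n, share, mean_d)
  yrs <- sort(unique(out$year))
  if (length(yrs) > 1) {
    first <- out[out$year == yrs[1], ]
    last <- out[out$year == yrs[length(yrs)], ]
    attr(out, "share_change") <- setNames(
      last$share[match(levels(q), last$quadrant)] -
        first$share[match(levels(q), first$quadrant)], levels(q))
  }
  out
}
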
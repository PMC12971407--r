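# Human activity intensity: HAI = SLUCC + PD + NTL on range-normalized
# components. The raw three-component sum lives on [0, 3]; it is divided
# by 3 so HAI shares the [0, 1] scale of EHI in the coupling model (a
# monotone, order-preserving rescale that leaves classifications
# unchanged).

#' Land-use disturbance weights
#'
#' Ordinal anthropogenic-disturbance weights per cover class:
#' construction 10, farmland 7, grassland 3, all other types 0.
#'
#' @return Named numeric vector over the six legend classes.
#' @export
lucc_weights <- function() {
  c(farmland = 7, forest = 0, grassland = 3, water = 0,
    construction = 10, desert = 0)
}

#' Land-use disturbance score SLUCC
#'
#' Per unit, the area-proportion-weighted mean of the class weights;
#' range [0, 10] under the default weights.
#'
#' @param props Tibble from [unit_class_proportions()].
#' @param weights Named weights per class, as [lucc_weights()].
#' @return Numeric vector of raw SLUCC per unit.
#' @export
slucc <- function(props, weights = lucc_weights()) {
  cls <- intersect(names(props),
                   c("farmland", "forest", "grassland", "water",
                     "construction", "desert"))
  miss <- setdiff(cls, names(weights))
  if (length(miss))
    stop("no disturbance weight for class(es): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(weights < 0)) stop("disturbance weights must be non-negative",
                             call. = FALSE)
  s <- rep(0, nrow(props))
  for (cl in cls) s <- s + props[[cl]] * weights[[cl]]
  s
}

#' Composite human activity intensity index
#'
#' Each component is min-max normalized across everything passed in (pool
#' all years first), summed, and divided by 3 so HAI lies in [0, 1].
#'
#' @param slucc_raw,pd,ntl Per-unit component vectors (raw scales).
#' @return Tibble `slucc_n`, `pd_n`, `ntl_n`, `hai`.
#' @export
hai_index <- function(slucc_raw, pd, ntl) {
  stopifnot(length(slucc_raw) == length(pd), length(pd) == length(ntl))
  sn <- minmax_norm(slucc_raw)
  pn <- minmax_norm(pd)
  nn <- minmax_norm(ntl)
  tibble::tibble(slucc_n = sn, pd_n = pn, ntl_n = nn,
                 hai = (sn + pn + nn) / 3)
}
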
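# Global Moran's I (univariate and bivariate) with seeded permutation
# inference, and Getis-Ord Gi* hot/cold-spot classification, over the
# regular unit lattice. Weights are stored as a sparse triplet list.

#' Build spatial weights over the unit lattice
#'
#' Contiguity (`queen`/`rook`) from (block_row, block_col) adjacency, or a
#' `distance_band` in lattice units. Units with no neighbors (islands) are
#' flagged; global statistics exclude them.
#'
#' @param units Tibble with `unit_id`, `block_row`, `block_col`.
#' @param scheme `"queen"`, `"rook"`, or `"distance_band"`.
#' @param standardization `"row"` (rows sum to 1) or `"binary"`.
#' @param d Band radius for `scheme = "distance_band"`.
#' @return An `eco_weights` list: `i`, `j`, `w` triplets (unit indices
#'   into `units`), `n`, `S0`, `islands`, `unit_id`.
#' @export
build_weights <- function(units, scheme = c("queen", "rook",
                                            "distance_band"),
                          standardization = c("row", "binary"), d = 1.5) {
  scheme <- match.arg(scheme)
  standardization <- match.arg(standardization)
  n <- nrow(units)
  stopifnot(n >= 2)
  r <- units$block_row; c <- units$block_col
  dr <- outer(r, r, "-"); dc <- outer(c, c, "-")
  adj <- switch(scheme,
    rook = (abs(dr) + abs(dc)) == 1,
    queen = pmax(abs(dr), abs(dc)) == 1,
    distance_band = {
      dd <- sqrt(dr^2 + dc^2)
      dd > 0 & dd <= d
    })
  idx <- which(adj, arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  w <- rep(1, length(i))
  islands <- setdiff(seq_len(n), unique(i))
  if (length(islands) == n)
    stop("all units are isolated; weights are empty", call. = FALSE)
  if (length(islands))
    message(length(islands), " island unit(s) excluded from global ",
            "statistics")
  if (standardization == "row") {
    deg <- tabulate(i, nbins = n)
    w <- w / deg[i]
  }
  structure(list(i = i, j = j, w = w, n = n, S0 = sum(w),
                 islands = islands, unit_id = units$unit_id,
                 scheme = scheme, standardization = standardization),
            class = "eco_weights")
}

#' Spatial weights as an adjacency table
#'
#' Flat `unit_i, unit_j, w` form (unit ids, not indices), convenient for
#' CSV export and cross-checking against other software.
#'
#' @param W An `eco_weights` from [build_weights()].
#' @return Tibble `unit_i`, `unit_j`, `w`.
#' @export
weights_table <- function(W) {
  tibble::tibble(unit_i = W$unit_id[W$i], unit_j = W$unit_id[W$j],
                 w = W$w)
}

# restrict weights to non-island units with finite x (reindexed)
active_weights <- function(W, keep) {
  map <- cumsum(keep)
  sel <- keep[W$i] & keep[W$j]
  list(i = map[W$i[sel]], j = map[W$j[sel]], w = W$w[sel],
       n = sum(keep), S0 = sum(W$w[sel]))
}

moran_stat <- function(z, Wa, denom) {
  Wa$n / Wa$S0 * sum(Wa$w * z[Wa$i] * z[Wa$j]) / denom
}

#' Global Moran's I with permutation inference
#'
#' `I = n * sum_ij w_ij (x_i - xbar)(x_j - xbar) / (S0 * sum_i (x_i -
#' xbar)^2)`. Significance comes from seeded random relabeling; the
#' one-sided p (toward the observed sign) is primary, with the two-sided
#' value alongside.
#'
#' @param x Unit values aligned with the weights' unit order.
#' @param W An `eco_weights` from [build_weights()].
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List of class `moran_result`: `I`, `expected` (-1/(n-1)),
#'   `p_value` (one-sided), `p_two_sided`, `z_score`, `n_perm`, `seed`,
#'   `n`.
#' @export
morans_i <- function(x, W, n_perm = 999, seed = 1) {
  keep <- rep(TRUE, W$n)
  keep[W$islands] <- FALSE
  keep <- keep & is.finite(x)
  xa <- x[keep]
  if (var(xa) <= 0)
    stop("zero variance: Moran's I is undefined", call. = FALSE)
  Wa <- active_weights(W, keep)
  z <- xa - mean(xa)
  denom <- sum(z^2)
  I <- moran_stat(z, Wa, denom)
  p_one <- p_two <- zsc <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    sims <- replicate(n_perm, {
      zp <- z[sample.int(Wa$n)]
      moran_stat(zp, Wa, sum(zp^2))
    })
    ge <- sum(sims >= I); le <- sum(sims <= I)
    p_one <- (min(ge, le) + 1) / (n_perm + 1)
    p_two <- min(1, 2 * p_one)
    zsc <- (I - mean(sims)) / sd(sims)
  }
  structure(list(I = I, expected = -1 / (Wa$n - 1),
                 p_value = p_one, p_two_sided = p_two,
                 z_score = zsc,
                 n_perm = n_perm, seed = seed, n = Wa$n),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f, n = %d)\n",
              x$I, x$expected, x$n))
  cat(sprintf("permutation p = %.4g (one-sided, %d permutations), z = %.2f\n",
              x$p_value, x$n_perm, x$z_score))
  invisible(x)
}

#' Bivariate global Moran's I
#'
#' `I_xy = sum_ij w_ij z_i^x z_j^y / S0` on z-scored variables; the
#' permutation null relabels `y` only, keeping the spatial arrangement of
#' `x` fixed.
#'
#' @param x,y Unit value vectors.
#' @param W An `eco_weights`.
#' @param n_perm,seed As in [morans_i()].
#' @return A `moran_result` list.
#' @export
bivariate_morans_i <- function(x, y, W, n_perm = 999, seed = 1) {
  keep <- rep(TRUE, W$n)
  keep[W$islands] <- FALSE
  keep <- keep & is.finite(x) & is.finite(y)
  xa <- x[keep]; ya <- y[keep]
  if (var(xa) <= 0 || var(ya) <= 0)
    stop("zero variance: bivariate Moran's I is undefined", call. = FALSE)
  Wa <- active_weights(W, keep)
  zx <- (xa - mean(xa)) / sd(xa) * sqrt(Wa$n / (Wa$n - 1))
  zy <- (ya - mean(ya)) / sd(ya) * sqrt(Wa$n / (Wa$n - 1))
  stat <- function(zyy) sum(Wa$w * zx[Wa$i] * zyy[Wa$j]) / Wa$S0
  I <- stat(zy)
  p_one <- p_two <- zsc <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    sims <- replicate(n_perm, stat(zy[sample.int(Wa$n)]))
    ge <- sum(sims >= I); le <- sum(sims <= I)
    p_one <- (min(ge, le) + 1) / (n_perm + 1)
    p_two <- min(1, 2 * p_one)
    zsc <- (I - mean(sims)) / sd(sims)
  }
  structure(list(I = I, expected = 0, p_value = p_one,
                 p_two_sided = p_two,
                 z_score = zsc,
                 n_perm = n_perm, seed = seed, n = Wa$n),
            class = "moran_result")
}

#' Getis-Ord Gi* hot/cold-spot statistic
#'
#' z-form Gi* with the focal unit included in its own neighborhood.
#' Hotspot classes follow the 1.65 / 1.96 / 2.58 confidence ladder
#' (90/95/99%).
#'
#' @param x Unit values.
#' @param W An `eco_weights` (self-neighbors are added internally).
#' @return Tibble `unit_id`, `gi_star`, `class` in
#'   `{cold99, cold95, cold90, ns, hot90, hot95, hot99}`.
#' @export
getis_ord_gstar <- function(x, W) {
  n <- W$n
  stopifnot(n >= 3)
  if (var(x, na.rm = TRUE) <= 0)
    stop("zero variance: Gi* is undefined", call. = FALSE)
  # self-included binary weights
  i <- c(W$i, seq_len(n)); j <- c(W$j, seq_len(n))
  w <- rep(1, length(i))
  xbar <- mean(x)
  S <- sqrt(sum(x^2) / n - xbar^2)
  sw <- tabulate(i, nbins = n)            # sum_j w_ij
  sw2 <- sw                               # binary: w^2 = w
  lag <- rep(0, n)
  agg <- tapply(x[j], i, sum)
  lag[as.integer(names(agg))] <- as.numeric(agg)
  denom <- S * sqrt((n * sw2 - sw^2) / (n - 1))
  g <- (lag - xbar * sw) / denom
  cls <- cut(g, breaks = c(-Inf, -2.58, -1.96, -1.65, 1.65, 1.96, 2.58, Inf),
             labels = c("cold99", "cold95", "cold90", "ns", "hot90",
                        "hot95", "hot99"))
  tibble::tibble(unit_id = W$unit_id, gi_star = as.numeric(g),
                 class = as.character(cls))
}
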
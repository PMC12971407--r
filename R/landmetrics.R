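# Landscape pattern metrics (SHDI, SHEI, DIVISION, IJI, CONTAG, area-
# weighted FRAC) per analysis unit, and the organization index EO that
# combines them. Conventions follow FRAGSTATS: patch connectivity is
# configurable (default 8), perimeters and adjacencies always use the
# 4-neighborhood, CONTAG adjacencies are double-counted with landscape-
# boundary edges excluded.

#' Delineate patches in a categorical grid
#'
#' Connected components per class (union-find), deterministic scanline
#' (row-major) label order. Perimeters count every 4-neighbor cell edge
#' bordering a different label, a masked cell, or the grid boundary.
#'
#' @param cat An [eco_catgrid()].
#' @param connectivity 4 or 8.
#' @return List: `labels` (integer matrix, 0 = background) and `patches`
#'   (tibble `patch_id`, `code`, `area` in cells, `perimeter` in cell
#'   edges).
#' @export
label_patches <- function(cat, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  codes <- cat$codes
  ok <- !cat$nodata_mask
  if (!any(ok)) stop("empty landscape: all cells masked", call. = FALSE)
  nr <- nrow(codes); nc <- ncol(codes)
  n <- nr * nc
  # row-major linear index so scanline order is natural
  rid <- function(r, c) (r - 1L) * nc + c
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offs <- list(c(0L, -1L), c(-1L, 0L))
  if (connectivity == 8) offs <- c(offs, list(c(-1L, -1L), c(-1L, 1L)))
  R <- row(codes); C <- col(codes)
  for (o in offs) {
    r2 <- R + o[1]; c2 <- C + o[2]
    sel <- ok & r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    sel[sel] <- ok[cbind(r2[sel], c2[sel])] &
      codes[sel] == codes[cbind(r2[sel], c2[sel])]
    ia <- rid(R[sel], C[sel])
    ib <- rid(r2[sel], c2[sel])
    for (k in seq_along(ia)) {
      ra <- find(ia[k]); rb <- find(ib[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- integer(n)
  lin <- rid(R, C)
  for (i in seq_len(n)) roots[i] <- find(i)
  labels <- matrix(0L, nr, nc)
  root_m <- matrix(0L, nr, nc)
  root_m[cbind(as.vector(R), as.vector(C))] <- roots[as.vector(lin)]
  valid_roots <- root_m[ok]
  # first-appearance order along scanline (row-major)
  ordroots <- root_m[ok][order(lin[ok])]
  uid <- unique(ordroots)
  lab_of <- setNames(seq_along(uid), uid)
  labels[ok] <- lab_of[as.character(valid_roots)]
  # per-patch records
  area <- tabulate(labels[ok], nbins = length(uid))
  code_of <- integer(length(uid))
  code_of[labels[ok]] <- codes[ok]
  # perimeter: count 4-edges to different label / mask / boundary
  pad <- function(m, dr, dc) {
    out <- matrix(0L, nr, nc)
    rs <- (1:nr) + dr; cs <- (1:nc) + dc
    okr <- rs >= 1 & rs <= nr; okc <- cs >= 1 & cs <= nc
    out[okr, okc] <- m[rs[okr], cs[okc]]
    out
  }
  per_cell <- matrix(0L, nr, nc)
  for (o in list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L))) {
    nb <- pad(labels, o[1], o[2])
    per_cell <- per_cell + (labels != nb)
  }
  perim <- as.integer(tapply(per_cell[ok], labels[ok], sum))
  list(labels = labels,
       patches = tibble::tibble(patch_id = seq_along(uid),
                                code = code_of, area = area,
                                perimeter = perim))
}

#' Shannon diversity index
#' @param p Class proportions (zero entries dropped; must sum to 1).
#' @return `-sum(p * log(p))`, >= 0.
#' @export
shdi <- function(p) {
  p <- p[p > 0]
  if (abs(sum(p) - 1) > 1e-8)
    stop("class proportions must sum to 1", call. = FALSE)
  -sum(p * log(p))
}

#' Shannon evenness index
#' @param p Class proportions.
#' @return SHDI / log(m); 0 for a single-class landscape.
#' @export
shei <- function(p) {
  p <- p[p > 0]
  m <- length(p)
  if (m <= 1) return(0)
  shdi(p) / log(m)
}

#' Landscape division index
#'
#' Probability that two random cells fall in different patches:
#' `1 - sum((a_ij / A)^2)`.
#'
#' @param patches Patch tibble from [label_patches()].
#' @param total_area Landscape area in cells (defaults to sum of patch
#'   areas).
#' @return Value in [0, 1].
#' @export
division <- function(patches, total_area = sum(patches$area)) {
  stopifnot(total_area > 0)
  1 - sum((patches$area / total_area)^2)
}

#' Area-weighted mean fractal dimension
#'
#' Per patch `2 * log(0.25 * perimeter) / log(area)` with lengths in linear
#' units (`cell_size`); single-cell patches take the limit value 1.
#' Patches are weighted by area.
#'
#' @param patches Patch tibble from [label_patches()].
#' @param cell_size Cell edge length.
#' @return Value in [1, 2].
#' @export
frac_am <- function(patches, cell_size = 1) {
  a <- patches$area * cell_size^2
  p <- patches$perimeter * cell_size
  f <- ifelse(patches$area <= 1, 1, 2 * log(0.25 * p) / log(a))
  sum(f * a) / sum(a)
}

#' Interspersion and juxtaposition index
#'
#' Evenness of inter-class edge lengths over the `m(m-1)/2` class pairs,
#' scaled to [0, 100]. Undefined (NA) for fewer than 3 classes or no
#' inter-class edge.
#'
#' @param e_ik Named or unnamed vector of inter-class edge lengths, one
#'   entry per unordered class pair (zeros allowed).
#' @param m Number of classes present.
#' @return Value in [0, 100], or NA when undefined.
#' @export
iji <- function(e_ik, m) {
  E <- sum(e_ik)
  if (m < 3 || E <= 0) return(NA_real_)
  q <- e_ik[e_ik > 0] / E
  100 * (-sum(q * log(q))) / log(0.5 * m * (m - 1))
}

#' Contagion index
#'
#' `100 * (1 + sum(q_ik * log(q_ik)) / (2 log m))` with
#' `q_ik = P_i * g_ik / sum_k(g_ik)`, adjacencies `g_ik` double-counted on
#' the 4-neighborhood. Zero `q` terms are skipped; a single-class
#' landscape returns 100.
#'
#' @param p Named class proportions (names = class codes as character).
#' @param g Square adjacency-count matrix with matching dimnames.
#' @param m Number of classes present.
#' @return Value in [0, 100].
#' @export
contag <- function(p, g, m) {
  if (m <= 1) return(100)
  s <- 0
  rows <- rownames(g)
  for (i in rows) {
    gi <- sum(g[i, ])
    if (gi <= 0) next
    q <- p[[i]] * g[i, ] / gi
    q <- q[q > 0]
    s <- s + sum(q * log(q))
  }
  100 * (1 + s / (2 * log(m)))
}

# adjacency bookkeeping on the 4-neighborhood, boundary and mask excluded
adjacency_counts <- function(cat) {
  codes <- cat$codes
  ok <- !cat$nodata_mask
  nr <- nrow(codes); nc <- ncol(codes)
  pairs_a <- integer(0); pairs_b <- integer(0)
  if (nc > 1) {
    sel <- ok[, -nc, drop = FALSE] & ok[, -1, drop = FALSE]
    pairs_a <- c(pairs_a, codes[, -nc, drop = FALSE][sel])
    pairs_b <- c(pairs_b, codes[, -1, drop = FALSE][sel])
  }
  if (nr > 1) {
    sel <- ok[-nr, , drop = FALSE] & ok[-1, , drop = FALSE]
    pairs_a <- c(pairs_a, codes[-nr, , drop = FALSE][sel])
    pairs_b <- c(pairs_b, codes[-1, , drop = FALSE][sel])
  }
  cls <- sort(unique(codes[ok]))
  g <- matrix(0, length(cls), length(cls),
              dimnames = list(as.character(cls), as.character(cls)))
  if (length(pairs_a)) {
    t1 <- table(factor(pairs_a, levels = cls), factor(pairs_b, levels = cls))
    g <- unclass(t1) + t(unclass(t1))  # double count both directions
  }
  g
}

#' All six pattern metrics for one landscape
#'
#' Treats the whole grid passed in as a single landscape (use
#' [unit_metrics()] for per-unit evaluation). Undefined metrics are NA.
#'
#' @param cat An [eco_catgrid()].
#' @param connectivity Patch connectivity, 4 or 8.
#' @return One-row tibble: `shdi`, `shei`, `division`, `iji`, `contag`,
#'   `frac_am`, `m`.
#' @export
landscape_metrics <- function(cat, connectivity = 8) {
  ok <- !cat$nodata_mask
  if (!any(ok)) stop("empty landscape: all cells masked", call. = FALSE)
  codes <- cat$codes[ok]
  tab <- table(codes)
  p <- as.numeric(tab) / length(codes)
  names(p) <- names(tab)
  m <- length(p)
  ps <- label_patches(cat, connectivity)
  g <- adjacency_counts(cat)
  e_ik <- c()
  if (m >= 2) {
    cls <- rownames(g)
    for (i in seq_len(m - 1)) for (k in (i + 1):m)
      e_ik <- c(e_ik, g[cls[i], cls[k]] / 2)  # single-count edge lengths
  }
  tibble::tibble(
    shdi = shdi(p),
    shei = shei(p),
    division = division(ps$patches, total_area = length(codes)),
    iji = iji(e_ik, m),
    contag = contag(p, g, m),
    frac_am = frac_am(ps$patches, cat$cell_size),
    m = m
  )
}

#' Per-unit landscape metrics
#'
#' Each analysis unit's sub-raster is treated as its own landscape.
#' Metrics that are undefined for a unit (e.g. IJI with fewer than three
#' classes) are recorded as NA, not zero.
#'
#' @param cat An [eco_catgrid()].
#' @param unit_cells Block edge in cells.
#' @param connectivity Patch connectivity.
#' @return Tibble keyed by `unit_id`, `block_row`, `block_col` with the
#'   six metrics and `m`.
#' @export
unit_metrics <- function(cat, unit_cells, connectivity = 8) {
  base <- suppressMessages(
    aggregate_to_units(cat, unit_cells, "mode"))
  res <- lapply(seq_len(nrow(base)), function(i) {
    sub <- unit_subgrid(cat, base$block_row[i], base$block_col[i],
                        unit_cells)
    landscape_metrics(sub, connectivity)
  })
  out <- dplyr::bind_cols(base[c("unit_id", "block_row", "block_col")],
                          dplyr::bind_rows(res))
  n_single <- sum(out$m < 2)
  if (n_single > 0)
    message(n_single, " unit(s) contain a single class; ",
            "SHEI/CONTAG take their degenerate conventions there")
  attr(out, "n_block_rows") <- attr(base, "n_block_rows")
  attr(out, "n_block_cols") <- attr(base, "n_block_cols")
  out
}

#' Organization-index weights
#'
#' Flat mode applies the six published sub-weights directly (they sum to
#' 1); nested mode applies the grouped form EO = 0.3001 LC + 0.4366 LH +
#' 0.2633 IC with LC/LH/IC built from the same sub-weights, which
#' double-applies the group coefficients — both are provided because the
#' source tables print the nested form while only the flat form keeps EO
#' on [0, 1] with unit total weight.
#'
#' @return Named list of sub-weights and group weights.
#' @export
eo_weights <- function() {
  list(shdi = 0.1499, shei = 0.1502, division = 0.1002,
       iji = 0.2173, contag = 0.1191, frac_am = 0.2633,
       group = c(LC = 0.3001, LH = 0.4366, IC = 0.2633))
}

#' Organization index EO per unit
#'
#' Min-max normalizes each metric across all rows passed in (pool years
#' before calling for a temporally comparable scale), imputes missing
#' metrics with the cross-unit median, and combines with the published
#' weights.
#'
#' @param records Tibble from [unit_metrics()] (optionally with a `year`
#'   column; normalization pools everything present).
#' @param mode `"flat"` (default) or `"nested"`.
#' @return `records` with normalized metric columns (`*_n`) and `eo`.
#' @export
organization_index <- function(records, mode = c("flat", "nested")) {
  mode <- match.arg(mode)
  w <- eo_weights()
  mets <- c("shdi", "shei", "division", "iji", "contag", "frac_am")
  out <- records
  for (mcol in mets) {
    x <- records[[mcol]]
    n_missing <- sum(is.na(x))
    if (n_missing == length(x)) {
      # undefined for every unit (e.g. IJI on single-class landscapes):
      # carries no information, pinned to mid-scale like a constant
      warning(mcol, " is undefined for every unit; normalized to 0.5",
              call. = FALSE)
      out[[paste0(mcol, "_n")]] <- rep(0.5, length(x))
      next
    }
    if (n_missing > 0) {
      x[is.na(x)] <- median(x, na.rm = TRUE)
      message(n_missing, " missing ", mcol,
              " value(s) imputed with the cross-unit median")
    }
    out[[paste0(mcol, "_n")]] <- minmax_norm(x)
  }
  if (mode == "flat") {
    out$eo <- w$shdi * out$shdi_n + w$shei * out$shei_n +
      w$division * out$division_n + w$iji * out$iji_n +
      w$contag * out$contag_n + w$frac_am * out$frac_am_n
  } else {
    lc <- w$shdi * out$shdi_n + w$shei * out$shei_n
    lh <- w$division * out$division_n + w$iji * out$iji_n +
      w$contag * out$contag_n
    ic <- w$frac_am * out$frac_am_n
    out$eo <- w$group[["LC"]] * lc + w$group[["LH"]] * lh +
      w$group[["IC"]] * ic
  }
  out
}
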
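#' @importFrom stats median sd var quantile fft rnorm runif setNames complete.cases predict cor
#' @importFrom utils head tail write.csv read.csv
NULL

#' Six-class land-cover legend
#'
#' Integer codes for the fixed legend used throughout the package:
#' farmland, forest, grassland, water, construction, desert.
#'
#' @return Named integer vector mapping class name to code.
#' @export
lc_legend <- function() {
  c(farmland = 1L, forest = 2L, grassland = 3L,
    water = 4L, construction = 5L, desert = 6L)
}

#' Construct a continuous raster grid
#'
#' The atomic spatial layer: a single 2D band with cell size, upper-left
#' origin and a nodata mask. Row 1 is the top row; indices are row-major.
#'
#' @param values Numeric matrix of cell values.
#' @param cell_size Edge length of a cell in map units (> 0).
#' @param origin Numeric `(x, y)` of the upper-left corner.
#' @param nodata_mask Logical matrix, `TRUE` where the cell is nodata.
#'   Defaults to `is.na(values)`.
#' @param crs_tag Opaque CRS label carried through I/O.
#' @return An object of class `eco_grid`.
#' @export
eco_grid <- function(values, cell_size = 1, origin = c(0, 0),
                     nodata_mask = NULL, crs_tag = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(nodata_mask)) nodata_mask <- is.na(values)
  nodata_mask <- matrix(as.logical(nodata_mask), nrow(values), ncol(values))
  stopifnot(identical(dim(values), dim(nodata_mask)), cell_size > 0)
  values[nodata_mask] <- NA_real_
  structure(list(values = values, cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin), nodata_mask = nodata_mask,
                 crs_tag = as.character(crs_tag)),
            class = "eco_grid")
}

#' Construct a categorical land-cover grid
#'
#' @param codes Integer matrix of class codes.
#' @param legend Named integer vector mapping class names to codes
#'   (at most the six classes of [lc_legend()]).
#' @param cell_size,origin,nodata_mask,crs_tag As in [eco_grid()].
#' @return An object of class `eco_catgrid`.
#' @export
eco_catgrid <- function(codes, legend = lc_legend(), cell_size = 1,
                        origin = c(0, 0), nodata_mask = NULL, crs_tag = "") {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (is.null(nodata_mask)) nodata_mask <- is.na(codes)
  nodata_mask <- matrix(as.logical(nodata_mask), nrow(codes), ncol(codes))
  stopifnot(identical(dim(codes), dim(nodata_mask)))
  if (length(legend) > 6L)
    stop("legend has more than 6 entries", call. = FALSE)
  bad <- setdiff(unique(codes[!nodata_mask]), unname(legend))
  if (length(bad))
    stop("codes outside legend: ", paste(bad, collapse = ", "), call. = FALSE)
  codes[nodata_mask] <- NA_integer_
  structure(list(codes = codes, legend = legend,
                 cell_size = as.numeric(cell_size), origin = as.numeric(origin),
                 nodata_mask = nodata_mask, crs_tag = as.character(crs_tag)),
            class = "eco_catgrid")
}

#' @export
print.eco_grid <- function(x, ...) {
  v <- x$values[!x$nodata_mask]
  cat(sprintf("<eco_grid> %d x %d, cell %g, %d valid cells, range [%g, %g]\n",
              nrow(x$values), ncol(x$values), x$cell_size, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' @export
print.eco_catgrid <- function(x, ...) {
  tab <- table(factor(x$codes[!x$nodata_mask], levels = unname(x$legend),
                      labels = names(x$legend)))
  cat(sprintf("<eco_catgrid> %d x %d, cell %g\n",
              nrow(x$codes), ncol(x$codes), x$cell_size))
  print(tab)
  invisible(x)
}

# ---- on-disk formats -------------------------------------------------------

write_asc <- function(values, path, cell_size, origin, nodata = -9999) {
  nr <- nrow(values); nc <- ncol(values)
  v <- values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", nc), sprintf("nrows %d", nr),
           sprintf("xllcorner %.10g", origin[1]),
           sprintf("yllcorner %.10g", origin[2] - nr * cell_size),
           sprintf("cellsize %.10g", cell_size),
           sprintf("NODATA_value %g", nodata))
  body <- apply(v, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
}

read_asc <- function(path) {
  ln <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1L
  while (i <= length(ln) && grepl("^[A-Za-z]", ln[i])) {
    kv <- strsplit(trimws(ln[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not a valid ASCII grid header: ", path, call. = FALSE)
  vals <- scan(text = paste(ln[i:length(ln)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc)
    stop("ASCII grid body size mismatch in ", path, call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m[m == nodata] <- NA_real_
  cs <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0
  list(values = m, cell_size = cs, origin = c(xll, yll + nr * cs))
}

#' Read a raster layer from disk
#'
#' Reads single-band ESRI ASCII grids (`.asc`), the package's plain-text
#' raster format. Nodata cells in the file become masked cells.
#'
#' @param path File to read.
#' @param kind `"continuous"` (default) or `"categorical"`. Categorical
#'   loads validate every code against `legend`.
#' @param legend Legend for categorical loads.
#' @return An [eco_grid()] or [eco_catgrid()].
#' @export
load_grid <- function(path, kind = c("continuous", "categorical"),
                      legend = lc_legend()) {
  kind <- match.arg(kind)
  if (!file.exists(path))
    stop("cannot read raster: ", path, call. = FALSE)
  g <- read_asc(path)
  if (kind == "continuous") {
    eco_grid(g$values, cell_size = g$cell_size, origin = g$origin)
  } else {
    codes <- g$values
    if (any(!is.na(codes) & codes != round(codes)))
      stop("categorical raster holds non-integer codes: ", path, call. = FALSE)
    eco_catgrid(matrix(as.integer(round(codes)), nrow(codes), ncol(codes)),
                legend = legend, cell_size = g$cell_size, origin = g$origin)
  }
}

#' Write a raster layer to disk
#'
#' Writes an ESRI ASCII grid with full double precision, so float32 (and
#' any shorter) payloads round-trip bit-identically through
#' [load_grid()].
#'
#' @param grid An [eco_grid()] or [eco_catgrid()].
#' @param path Destination (`.asc`).
#' @param nodata Nodata sentinel written to the header.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, nodata = -9999) {
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  vals <- if (inherits(grid, "eco_catgrid")) {
    m <- grid$codes; storage.mode(m) <- "double"; m
  } else grid$values
  write_asc(vals, path, grid$cell_size, grid$origin, nodata = nodata)
  invisible(path)
}

# ---- unit aggregation ------------------------------------------------------

block_index <- function(n, unit_cells) ceiling(seq_len(n) / unit_cells)

#' Aggregate a grid to square analysis units
#'
#' Partitions the raster into `unit_cells` x `unit_cells` blocks from the
#' top-left corner (edge blocks may be smaller) and computes one statistic
#' per block. Blocks with more than half of their nominal cells masked are
#' dropped. `mode` ties break to the smallest class code.
#'
#' @param grid An [eco_grid()] or (for `mode` / `proportion_of`) an
#'   [eco_catgrid()].
#' @param unit_cells Block edge in cells (>= 1).
#' @param statistic `"mean"`, `"sum"`, `"mode"`, or `"proportion_of"`.
#' @param code Class code for `statistic = "proportion_of"`.
#' @return A tibble with `unit_id`, `block_row`, `block_col`, `value`
#'   (class `eco_units` attribute columns `n_block_rows`, `n_block_cols`).
#' @export
aggregate_to_units <- function(grid, unit_cells,
                               statistic = c("mean", "sum", "mode",
                                             "proportion_of"),
                               code = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(unit_cells >= 1)
  categorical <- inherits(grid, "eco_catgrid")
  if (statistic == "proportion_of" && !categorical)
    stop("proportion_of requires a categorical grid", call. = FALSE)
  if (statistic %in% c("mean", "sum") && categorical)
    stop(statistic, " requires a continuous grid", call. = FALSE)
  vals <- if (categorical) grid$codes else grid$values
  nr <- nrow(vals); nc <- ncol(vals)
  br <- block_index(nr, unit_cells)
  bc <- block_index(nc, unit_cells)
  nbr <- max(br); nbc <- max(bc)
  cell_br <- br[row(vals)]
  cell_bc <- bc[col(vals)]
  bid <- (cell_br - 1L) * nbc + cell_bc
  valid <- !grid$nodata_mask
  n_valid <- tabulate(bid[valid], nbins = nbr * nbc)
  # nominal size: unit_cells^2 for interior, actual extent for edge blocks
  rows_in <- tabulate(br, nbins = nbr)
  cols_in <- tabulate(bc, nbins = nbc)
  nominal <- outer(rows_in, cols_in)  # block_row x block_col
  nominal <- as.vector(t(nominal))   # bid order: row-major over (br, bc)
  keep <- n_valid > 0.5 * nominal
  stat_val <- rep(NA_real_, nbr * nbc)
  f <- factor(bid[valid], levels = seq_len(nbr * nbc))
  v <- vals[valid]
  if (statistic == "mean") {
    s <- tapply(v, f, mean)
    stat_val <- as.numeric(s)
  } else if (statistic == "sum") {
    stat_val <- as.numeric(tapply(v, f, sum))
  } else if (statistic == "mode") {
    stat_val <- as.numeric(tapply(v, f, function(x) {
      tb <- table(x)
      as.numeric(names(tb))[which.max(tb)]  # ties: smallest code (table sorted)
    }))
  } else {
    stopifnot(!is.null(code))
    stat_val <- as.numeric(tapply(v, f, function(x) mean(x == code)))
  }
  ids <- which(keep)
  out <- tibble::tibble(
    unit_id = ids,
    block_row = (ids - 1L) %/% nbc + 1L,
    block_col = (ids - 1L) %% nbc + 1L,
    value = stat_val[ids]
  )
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(n_drop, " unit(s) dropped (mask-dominated or empty)")
  attr(out, "n_block_rows") <- nbr
  attr(out, "n_block_cols") <- nbc
  attr(out, "unit_cells") <- unit_cells
  out
}

#' Per-unit class proportions of a categorical grid
#'
#' @param cat An [eco_catgrid()].
#' @param unit_cells Block edge in cells.
#' @return Tibble `unit_id`, `block_row`, `block_col`, one proportion
#'   column per legend class (proportions of valid cells; rows sum to 1).
#' @export
unit_class_proportions <- function(cat, unit_cells) {
  base <- aggregate_to_units(cat, unit_cells, "proportion_of",
                             code = unname(cat$legend[1]))
  out <- base[c("unit_id", "block_row", "block_col")]
  for (cls in names(cat$legend)) {
    p <- suppressMessages(
      aggregate_to_units(cat, unit_cells, "proportion_of",
                         code = unname(cat$legend[cls])))
    out[[cls]] <- p$value[match(out$unit_id, p$unit_id)]
  }
  attr(out, "n_block_rows") <- attr(base, "n_block_rows")
  attr(out, "n_block_cols") <- attr(base, "n_block_cols")
  attr(out, "unit_cells") <- attr(base, "unit_cells")
  out
}

#' Extract the sub-raster of one analysis unit
#'
#' @param grid A grid object.
#' @param block_row,block_col Unit lattice position (1-based, from top-left).
#' @param unit_cells Block edge in cells.
#' @return A grid object of the same class covering only that block.
#' @export
unit_subgrid <- function(grid, block_row, block_col, unit_cells) {
  vals <- if (inherits(grid, "eco_catgrid")) grid$codes else grid$values
  nr <- nrow(vals); nc <- ncol(vals)
  rows <- ((block_row - 1L) * unit_cells + 1L):min(block_row * unit_cells, nr)
  cols <- ((block_col - 1L) * unit_cells + 1L):min(block_col * unit_cells, nc)
  if (inherits(grid, "eco_catgrid")) {
    eco_catgrid(grid$codes[rows, cols, drop = FALSE], legend = grid$legend,
                cell_size = grid$cell_size,
                nodata_mask = grid$nodata_mask[rows, cols, drop = FALSE])
  } else {
    eco_grid(grid$values[rows, cols, drop = FALSE],
             cell_size = grid$cell_size,
             nodata_mask = grid$nodata_mask[rows, cols, drop = FALSE])
  }
}

#' Min-max normalize a numeric vector to [0, 1]
#'
#' Pooled normalization helper used for EV, ESI indicators, HAI components
#' and landscape metrics: values are rescaled by the range over everything
#' passed in (pool all years before calling to get a temporally comparable
#' scale). A constant vector maps to 0.5 with a warning.
#'
#' @param x Numeric vector (NAs preserved).
#' @return Numeric vector in [0, 1].
#' @export
minmax_norm <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!is.finite(r[1]))
    stop("min-max normalization over all-missing input", call. = FALSE)
  if (r[2] - r[1] <= 0) {
    warning("constant indicator normalized to 0.5", call. = FALSE)
    return(ifelse(is.na(x), NA_real_, 0.5))
  }
  (x - r[1]) / (r[2] - r[1])
}
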
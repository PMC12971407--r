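# Independent brute-force oracles. These recompute quantities straight
# from their definitions (plain loops, dense matrices, exhaustive
# enumeration) and deliberately share no code with the implementation.

# ---- landscape metrics ------------------------------------------------

# BFS flood-fill patch extraction
oracle_patches <- function(codes, connectivity = 8) {
  nr <- nrow(codes); nc <- ncol(codes)
  seen <- matrix(FALSE, nr, nc)
  seen[is.na(codes)] <- TRUE
  offs <- if (connectivity == 8) {
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
          c(1, -1), c(1, 0), c(1, 1))
  } else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  patches <- list()
  for (r0 in 1:nr) for (c0 in 1:nc) {
    if (seen[r0, c0]) next
    cls <- codes[r0, c0]
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    cells <- list()
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      cells[[length(cells) + 1]] <- cur
      for (k in seq_len(nrow(offs))) {
        rr <- cur[1] + offs[k, 1]; cc <- cur[2] + offs[k, 2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            !seen[rr, cc] && !is.na(codes[rr, cc]) &&
            codes[rr, cc] == cls) {
          seen[rr, cc] <- TRUE
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
    cellm <- do.call(rbind, cells)
    # perimeter: 4-edges to different code cells / NA / boundary
    per <- 0
    for (k in seq_len(nrow(cellm))) {
      for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- cellm[k, 1] + o[1]; cc <- cellm[k, 2] + o[2]
        inside <- rr >= 1 && rr <= nr && cc >= 1 && cc <= nc
        same_patch <- inside && !is.na(codes[rr, cc]) &&
          any(cellm[, 1] == rr & cellm[, 2] == cc)
        if (!same_patch) per <- per + 1
      }
    }
    patches[[length(patches) + 1]] <-
      list(code = cls, area = nrow(cellm), perimeter = per)
  }
  patches
}

oracle_landscape_metrics <- function(codes, connectivity = 8,
                                     cell_size = 1) {
  valid <- codes[!is.na(codes)]
  A <- length(valid)
  tab <- table(valid)
  p <- as.numeric(tab) / A
  cls <- as.numeric(names(tab))
  m <- length(cls)
  o_shdi <- -sum(p * log(p))
  o_shei <- if (m <= 1) 0 else o_shdi / log(m)
  pat <- oracle_patches(codes, connectivity)
  areas <- vapply(pat, `[[`, 0, "area")
  pers <- vapply(pat, `[[`, 0, "perimeter")
  o_div <- 1 - sum((areas / A)^2)
  fr <- ifelse(areas <= 1, 1,
               2 * log(0.25 * pers * cell_size) /
                 log(areas * cell_size^2))
  o_frac <- sum(fr * areas) / sum(areas)
  # adjacencies: double count, boundary excluded
  nr <- nrow(codes); nc <- ncol(codes)
  g <- matrix(0, m, m, dimnames = list(cls, cls))
  for (r in 1:nr) for (c in 1:nc) {
    if (is.na(codes[r, c])) next
    for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + o[1]; cc <- c + o[2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
          !is.na(codes[rr, cc])) {
        i <- as.character(codes[r, c]); k <- as.character(codes[rr, cc])
        g[i, k] <- g[i, k] + 1
      }
    }
  }
  # IJI from single-count inter-class edges
  o_iji <- NA_real_
  if (m >= 3) {
    e <- c()
    for (i in 1:(m - 1)) for (k in (i + 1):m) e <- c(e, g[i, k] / 2)
    E <- sum(e)
    if (E > 0) {
      q <- e[e > 0] / E
      o_iji <- 100 * (-sum(q * log(q))) / log(0.5 * m * (m - 1))
    }
  }
  o_contag <- if (m <= 1) 100 else {
    s <- 0
    for (i in 1:m) {
      gi <- sum(g[i, ])
      if (gi > 0) for (k in 1:m) {
        q <- p[i] * g[i, k] / gi
        if (q > 0) s <- s + q * log(q)
      }
    }
    100 * (1 + s / (2 * log(m)))
  }
  list(shdi = o_shdi, shei = o_shei, division = o_div, iji = o_iji,
       contag = o_contag, frac_am = o_frac, m = m)
}

# ---- Moran's I (dense) ------------------------------------------------

oracle_moran_dense <- function(x, Wmat) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + Wmat[i, j] * z[i] * z[j]
  n * num / (sum(Wmat) * sum(z^2))
}

dense_from_weights <- function(W) {
  M <- matrix(0, W$n, W$n)
  M[cbind(W$i, W$j)] <- W$w
  M
}

# ---- entropy weights (step-by-step) -----------------------------------

oracle_entropy_weights <- function(X, eps = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X)
  w <- numeric(ncol(X))
  e <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    x[x < eps] <- eps
    pj <- x / sum(x)
    e[j] <- -sum(pj * log(pj)) / log(n)
  }
  d <- 1 - e
  d / sum(d)
}

# ---- Shapley enumeration over feature subsets -------------------------

# Exhaustive Shapley value for tree ensembles in which every tree splits
# on a single feature (depth 1): v(S) evaluates each tree at x when its
# feature is in S and at its cover-weighted expectation otherwise.
oracle_shapley_depth1 <- function(trees, x, features) {
  # trees: list of list(feature, split, yes_value, no_value, yes_cover,
  #        no_cover); xgboost convention: x < split -> "yes" branch
  tree_val <- function(t, known) {
    if (t$feature %in% known) {
      if (x[[t$feature]] < t$split) t$yes_value else t$no_value
    } else {
      (t$yes_value * t$yes_cover + t$no_value * t$no_cover) /
        (t$yes_cover + t$no_cover)
    }
  }
  v <- function(S) sum(vapply(trees, tree_val, 0, known = S))
  n <- length(features)
  phi <- setNames(numeric(n), features)
  for (f in features) {
    others <- setdiff(features, f)
    for (k in 0:length(others)) {
      subsets <- if (k == 0) list(character(0)) else
        utils::combn(others, k, simplify = FALSE)
      for (S in subsets) {
        wgt <- factorial(length(S)) * factorial(n - length(S) - 1) /
          factorial(n)
        phi[f] <- phi[f] + wgt * (v(c(S, f)) - v(S))
      }
    }
  }
  phi
}

# pull depth-1 trees out of a fitted booster
extract_depth1_trees <- function(model) {
  dt <- xgboost::xgb.model.dt.tree(model = model)
  val_col <- intersect(c("Quality", "Gain"), names(dt))[1]
  trees <- list()
  for (tr in unique(dt$Tree)) {
    sub <- dt[dt$Tree == tr, ]
    root <- sub[sub$Node == 0, ]
    stopifnot(root$Feature != "Leaf")
    yes_id <- root$Yes; no_id <- root$No
    yes <- sub[sub$ID == yes_id, ]
    no <- sub[sub$ID == no_id, ]
    stopifnot(yes$Feature == "Leaf", no$Feature == "Leaf")
    trees[[length(trees) + 1]] <- list(
      feature = root$Feature, split = as.numeric(root$Split),
      yes_value = yes[[val_col]], no_value = no[[val_col]],
      yes_cover = yes$Cover, no_cover = no$Cover)
  }
  trees
}

# ---- misc helpers -----------------------------------------------------

random_catgrid <- function(nr, nc, k = 3, seed = 1) {
  set.seed(seed)
  eco_catgrid(matrix(sample.int(k, nr * nc, replace = TRUE), nr, nc))
}

lag1_autocorr <- function(m) {
  a <- as.vector(m[, -ncol(m)]); b <- as.vector(m[, -1])
  c1 <- cor(a, b)
  a <- as.vector(m[-nrow(m), ]); b <- as.vector(m[-1, ])
  (c1 + cor(a, b)) / 2
}
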
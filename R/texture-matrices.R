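# Grey-level texture matrices on masked 3D integer-level arrays.
#
# All builders take `lev`: an integer 3D array of grey levels 1..ng with NA
# at out-of-mask positions. Neighbourhoods are 26-connected (Chebyshev
# distance 1); directed quantities use the 13 unique 3D directions (one per
# antipodal pair).

#' The 13 unique 3D directions at Chebyshev distance 1
#'
#' One representative per antipodal pair of the 26 unit-cube neighbour
#' offsets, used for GLCM and GLRLM direction sets.
#'
#' @return A 13 x 3 integer matrix of offsets.
#' @export
unique_directions_3d <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  m <- g[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  rownames(m) <- NULL
  m
}

# Index ranges such that src + d stays inside dim dm (empty when the shift
# exceeds the axis extent).
shift_ranges <- function(dm, d) {
  lapply(1:3, function(a) {
    from <- max(1L, 1L - d[a])
    to <- min(dm[a], dm[a] - d[a])
    if (from > to) integer(0) else from:to
  })
}

# All (level_src, level_dst) pairs along direction d where both ends are
# in-mask. Returns a 2-column matrix, or NULL when the direction leaves the
# array entirely.
level_pairs <- function(lev, d) {
  dm <- dim(lev)
  r <- shift_ranges(dm, d)
  if (any(vapply(r, length, 1L) == 0L)) return(NULL)
  a <- lev[r[[1]], r[[2]], r[[3]], drop = FALSE]
  b <- lev[r[[1]] + d[1], r[[2]] + d[2], r[[3]] + d[3], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  cbind(a[ok], b[ok])
}

# Symmetrized, normalized co-occurrence matrix for one direction, or NULL if
# the direction yields no in-mask pairs.
glcm_matrix <- function(lev, ng, d) {
  pr <- level_pairs(lev, d)
  if (is.null(pr)) return(NULL)
  cnt <- tabulate((pr[, 2] - 1L) * ng + pr[, 1], nbins = ng * ng)
  m <- matrix(cnt, ng, ng)
  m <- m + t(m)
  m / sum(m)
}

# Run-length count matrix (levels x run length) for one direction. Runs are
# maximal same-level segments along the direction's lines; NA (out-of-mask)
# breaks runs. Vectorized by sorting voxels into (line, step) order.
glrlm_matrix <- function(lev, ng, d) {
  dm <- dim(lev)
  idx <- arrayInd(seq_along(lev), dm)
  a <- which(d != 0)[1]
  t_along <- idx[, a] * d[a]
  k1 <- idx[, 1] - t_along * d[1]
  k2 <- idx[, 2] - t_along * d[2]
  k3 <- idx[, 3] - t_along * d[3]
  ord <- order(k1, k2, k3, t_along)
  v <- lev[ord]
  n <- length(v)
  same_line <- k1[ord][-1] == k1[ord][-n] & k2[ord][-1] == k2[ord][-n] &
    k3[ord][-1] == k3[ord][-n]
  same_lev <- !is.na(v[-1]) & !is.na(v[-n]) & v[-1] == v[-n]
  run_id <- cumsum(c(TRUE, !(same_line & same_lev)))
  keep <- !is.na(v)
  if (!any(keep)) return(matrix(0, ng, 1))
  rid <- run_id[keep]
  len <- tabulate(match(rid, unique(rid)))
  rlev <- v[keep][!duplicated(rid)]
  lmax <- max(len)
  cnt <- tabulate((len - 1L) * ng + rlev, nbins = ng * lmax)
  matrix(cnt, ng, lmax)
}

# 26-connected zones of equal grey level; returns a data.frame with one row
# per zone (level, size). Union-find over same-level neighbour pairs.
glszm_zones <- function(lev) {
  dm <- dim(lev)
  lin <- array(seq_along(lev), dm)
  parent <- seq_along(lev)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  dirs <- unique_directions_3d()
  for (k in seq_len(nrow(dirs))) {
    d <- dirs[k, ]
    r <- shift_ranges(dm, d)
    if (any(vapply(r, length, 1L) == 0L)) next
    a <- lev[r[[1]], r[[2]], r[[3]], drop = FALSE]
    b <- lev[r[[1]] + d[1], r[[2]] + d[2], r[[3]] + d[3], drop = FALSE]
    ia <- lin[r[[1]], r[[2]], r[[3]], drop = FALSE]
    ib <- lin[r[[1]] + d[1], r[[2]] + d[2], r[[3]] + d[3], drop = FALSE]
    ok <- !is.na(a) & !is.na(b) & a == b
    if (!any(ok)) next
    ia <- ia[ok]; ib <- ib[ok]
    for (p in seq_along(ia)) {
      ra <- find_root(ia[p]); rb <- find_root(ib[p])
      if (ra != rb) parent[ra] <- rb
    }
  }
  members <- which(!is.na(lev))
  roots <- vapply(members, find_root, 1L)
  sz <- table(roots)
  data.frame(level = as.integer(lev[as.integer(names(sz))]),
             size = as.integer(sz))
}

glszm_matrix <- function(lev, ng) {
  z <- glszm_zones(lev)
  smax <- max(z$size)
  cnt <- tabulate((z$size - 1L) * ng + z$level, nbins = ng * smax)
  matrix(cnt, ng, smax)
}

# Count, per in-mask voxel, the 26-neighbours (in-mask) with the same level.
equal_neighbour_counts <- function(lev) {
  dm <- dim(lev)
  cnt <- array(0L, dm)
  dirs <- unique_directions_3d()
  for (k in seq_len(nrow(dirs))) {
    for (sgn in c(1L, -1L)) {
      d <- sgn * dirs[k, ]
      r <- shift_ranges(dm, d)
      if (any(vapply(r, length, 1L) == 0L)) next
      a <- lev[r[[1]], r[[2]], r[[3]], drop = FALSE]
      b <- lev[r[[1]] + d[1], r[[2]] + d[2], r[[3]] + d[3], drop = FALSE]
      eq <- !is.na(a) & !is.na(b) & a == b
      cnt[r[[1]], r[[2]], r[[3]]] <-
        cnt[r[[1]], r[[2]], r[[3]], drop = FALSE] + eq
    }
  }
  cnt
}

# Dependence matrix: rows = grey level, columns = dependence + 1, where the
# dependence of a voxel is its number of in-mask 26-neighbours with the same
# level (similarity threshold 0).
gldm_matrix <- function(lev, ng) {
  dep <- equal_neighbour_counts(lev)
  inside <- !is.na(lev)
  j <- dep[inside] + 1L
  g <- lev[inside]
  jmax <- max(j)
  cnt <- tabulate((j - 1L) * ng + g, nbins = ng * jmax)
  matrix(cnt, ng, jmax)
}

# Neighbouring grey tone difference summaries: for each voxel with at least
# one in-mask 26-neighbour, the absolute difference between its level and the
# mean level of those neighbours, accumulated per grey level.
# Returns list(n_i, s_i, p_i, nvp) with vectors indexed 1..ng.
ngtdm_summaries <- function(lev, ng) {
  dm <- dim(lev)
  nb_sum <- array(0, dm)
  nb_cnt <- array(0L, dm)
  dirs <- unique_directions_3d()
  for (k in seq_len(nrow(dirs))) {
    for (sgn in c(1L, -1L)) {
      d <- sgn * dirs[k, ]
      r <- shift_ranges(dm, d)
      if (any(vapply(r, length, 1L) == 0L)) next
      b <- lev[r[[1]] + d[1], r[[2]] + d[2], r[[3]] + d[3], drop = FALSE]
      ok <- !is.na(b)
      bv <- b
      bv[!ok] <- 0L
      nb_sum[r[[1]], r[[2]], r[[3]]] <-
        nb_sum[r[[1]], r[[2]], r[[3]], drop = FALSE] + bv
      nb_cnt[r[[1]], r[[2]], r[[3]]] <-
        nb_cnt[r[[1]], r[[2]], r[[3]], drop = FALSE] + ok
    }
  }
  valid <- !is.na(lev) & nb_cnt > 0
  g <- lev[valid]
  diffs <- abs(g - nb_sum[valid] / nb_cnt[valid])
  n_i <- tabulate(g, nbins = ng)
  s_i <- vapply(seq_len(ng), function(i) sum(diffs[g == i]), 0)
  nvp <- sum(n_i)
  list(n_i = n_i, s_i = s_i, p_i = n_i / nvp, nvp = nvp)
}
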
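# Density-based clustering (DBSCAN) on planar coordinates.
#
# Used to label GPS stay clusters and flag low-density points (erroneous
# fixes, isolated positions) as noise. Distances are Euclidean in the input
# units (degrees for lat/lon). The implementation is exact DBSCAN with a
# grid index: cells of width eps/sqrt(2) guarantee that any two points
# sharing a cell are within eps, so heavily populated cells are core by
# construction and only sparse-cell points need explicit neighbour counts.

dist2 <- function(x1, y1, x2, y2) (x1 - x2)^2 + (y1 - y2)^2

#' DBSCAN cluster labels for 2-d points
#'
#' @param x,y numeric coordinate vectors.
#' @param eps neighbourhood radius (same units as the coordinates).
#' @param min_pts minimum number of points within `eps` (the point itself
#'   included) for a core point.
#' @return integer vector of cluster labels; 0 marks noise.
#' @export
dbscan_points <- function(x, y, eps, min_pts) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n == 0L) return(integer(0))
  if (n < min_pts) return(rep(0L, n))
  eps2 <- eps^2
  w <- eps / sqrt(2)
  cx <- as.integer(floor(x / w))
  cy <- as.integer(floor(y / w))
  cell_key <- paste(cx, cy)
  cells <- unique(data.table(cx = cx, cy = cy, ckey = cell_key))
  cell_of <- match(cell_key, cells$ckey)
  cell_count <- tabulate(cell_of, nbins = nrow(cells))
  cell_idx <- split(seq_len(n), cell_of)  # names are cell row numbers

  # candidate neighbour cells: Chebyshev distance <= 2 (eps < 3 cell widths)
  neighbour_cells <- function(ci) {
    keys <- as.vector(outer(cells$cx[ci] + (-2:2), cells$cy[ci] + (-2:2),
                            paste))
    m <- match(keys, cells$ckey)
    m[!is.na(m)]
  }

  # --- core determination -----------------------------------------------
  core <- logical(n)
  auto_cells <- which(cell_count >= min_pts)
  for (ci in auto_cells) core[cell_idx[[as.character(ci)]]] <- TRUE
  check_cells <- which(cell_count < min_pts)
  for (ci in check_cells) {
    pts <- cell_idx[[as.character(ci)]]
    cand <- unlist(cell_idx[as.character(neighbour_cells(ci))],
                   use.names = FALSE)
    if (length(cand) < min_pts) next
    d2 <- outer(x[pts], x[cand], "-")^2 + outer(y[pts], y[cand], "-")^2
    core[pts] <- rowSums(d2 <= eps2) >= min_pts
  }
  if (!any(core)) return(rep(0L, n))

  # --- connect core points across cells (union-find over cells) ---------
  parent <- seq_len(nrow(cells))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  core_cells <- sort(unique(cell_of[core]))
  core_in_cell <- split(which(core), cell_of[core])
  any_pair_close <- function(a, b) {
    # chunked scan with early exit; dense adjacent cells hit immediately
    step <- 256L
    for (s in seq(1L, length(a), by = step)) {
      aa <- a[s:min(s + step - 1L, length(a))]
      d2 <- outer(x[aa], x[b], "-")^2 + outer(y[aa], y[b], "-")^2
      if (any(d2 <= eps2)) return(TRUE)
    }
    FALSE
  }
  for (ci in core_cells) {
    for (cj in neighbour_cells(ci)) {
      if (cj <= ci || !cj %in% core_cells) next
      if (find(ci) == find(cj)) next
      if (any_pair_close(core_in_cell[[as.character(ci)]],
                         core_in_cell[[as.character(cj)]])) {
        union_(ci, cj)
      }
    }
  }
  cell_root <- vapply(seq_len(nrow(cells)), find, integer(1))
  roots <- sort(unique(cell_root[core_cells]))
  labels <- rep(0L, n)
  labels[core] <- match(cell_root[cell_of[core]], roots)

  # --- border points: non-core within eps of a core point ----------------
  for (ci in seq_len(nrow(cells))) {
    pts <- cell_idx[[as.character(ci)]]
    pts <- pts[!core[pts]]
    if (length(pts) == 0L) next
    cand <- unlist(core_in_cell[as.character(neighbour_cells(ci))],
                   use.names = FALSE)
    if (length(cand) == 0L) next
    d2 <- outer(x[pts], x[cand], "-")^2 + outer(y[pts], y[cand], "-")^2
    hit <- d2 <= eps2
    has <- rowSums(hit) > 0
    if (any(has)) {
      nearest <- cand[apply(d2[has, , drop = FALSE], 1L, which.min)]
      labels[pts[has]] <- labels[nearest]
    }
  }
  labels
}
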
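# Internal helpers shared across modules.

#' Round half-up
#'
#' Decimal rounding where ties go away from zero (base `round()` uses
#' banker's rounding). Diagnostic-accuracy tables in this field report
#' percentages rounded half-up to one decimal.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Derive a per-item 32-bit seed stream from one master seed.
# Deterministic, collision-free for i < 2^20 at any master < 2^31.
derive_seed <- function(master, i) {
  as.integer((as.double(master) * 48271 + as.double(i) * 1009 + 17) %%
    2147483647)
}

stopifnot_scalar <- function(x, what) {
  if (length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing value.", what))
  }
  invisible(x)
}

match_mass_type <- function(mass_type) {
  if (length(mass_type) != 1L || !mass_type %in% c("solid", "cystic", "mixed")) {
    abort("`mass_type` must be one of \"solid\", \"cystic\", \"mixed\".")
  }
  mass_type
}

match_menopausal <- function(menopausal) {
  if (!all(menopausal %in% c("pre", "post"))) {
    abort("`menopausal` must be \"pre\" or \"post\".")
  }
  menopausal
}

# Shoelace polygon area (positive regardless of orientation).
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

polygon_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}

# Segment-intersection test used by the topology checks: TRUE when the
# closed polygon has no two non-adjacent edges crossing.
is_simple_polygon <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) return(FALSE)
  p1 <- xy
  p2 <- xy[c(2:n, 1L), , drop = FALSE]
  cross <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  for (i in seq_len(n - 1L)) {
    if (i + 2L > n) next
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]
    if (!length(js)) next
    d1 <- cross(p1[i, 1], p1[i, 2], p2[i, 1], p2[i, 2], p1[js, 1], p1[js, 2])
    d2 <- cross(p1[i, 1], p1[i, 2], p2[i, 1], p2[i, 2], p2[js, 1], p2[js, 2])
    d3 <- cross(p1[js, 1], p1[js, 2], p2[js, 1], p2[js, 2],
                rep(p1[i, 1], length(js)), rep(p1[i, 2], length(js)))
    d4 <- cross(p1[js, 1], p1[js, 2], p2[js, 1], p2[js, 2],
                rep(p2[i, 1], length(js)), rep(p2[i, 2], length(js)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

# 8-connected component labelling of a logical matrix via igraph.
label_components8 <- function(mask) {
  idx <- which(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (!length(idx)) return(lab)
  nr <- nrow(mask)
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  pos <- integer(length(mask)); pos[idx] <- seq_along(idx)
  edges <- integer(0)
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rr + d[1]; c2 <- cc + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(mask)
    j <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- pos[j] > 0L
    if (any(hit)) {
      edges <- c(edges, rbind(pos[idx[ok]][hit], pos[j][hit]))
    }
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  lab[idx] <- igraph::components(g)$membership
  lab
}

largest_component8 <- function(mask) {
  lab <- label_components8(mask)
  if (!any(lab > 0L)) return(mask & FALSE)
  keep <- which.max(tabulate(lab[lab > 0L]))
  lab == keep
}
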
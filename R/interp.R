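# Scattered-data linear interpolation on a Delaunay triangulation
# (Bowyer-Watson), with nearest-neighbour fill outside the convex hull.
# Piecewise-linear barycentric interpolation reproduces planes exactly and
# equals the observed value at every data point.

# Circumcircle of triangle (p1, p2, p3); returns center and squared radius.
circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]
  bx <- p2[1]; by <- p2[2]
  cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-14) return(NULL)  # degenerate (collinear)
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(cx = ux, cy = uy, r2 = (ax - ux)^2 + (ay - uy)^2)
}

# Bowyer-Watson Delaunay triangulation of 2-D points (n x 2 matrix).
# Returns an m x 3 matrix of point indices. Coordinates are rescaled to
# [0,1] internally for numerical robustness.
delaunay <- function(pts) {
  n <- nrow(pts)
  if (n < 3) stop("interpolation error: need at least 3 points")
  rng_x <- range(pts[, 1]); rng_y <- range(pts[, 2])
  sx <- diff(rng_x); sy <- diff(rng_y)
  if (sx == 0 || sy == 0) {
    stop("interpolation error: points are collinear (degenerate axis)")
  }
  P <- cbind((pts[, 1] - rng_x[1]) / sx, (pts[, 2] - rng_y[1]) / sy)
  # super-triangle comfortably enclosing the unit square
  P <- rbind(P, c(-10, -10), c(10, -10), c(0.5, 20))
  st <- n + 1:3
  tris <- list(c(st[1], st[2], st[3]))
  circ <- list(circumcircle(P[st[1], ], P[st[2], ], P[st[3], ]))
  for (i in seq_len(n)) {
    px <- P[i, 1]; py <- P[i, 2]
    bad <- vapply(circ, function(cc) {
      !is.null(cc) && ((px - cc$cx)^2 + (py - cc$cy)^2) <= cc$r2 * (1 + 1e-12)
    }, TRUE)
    # boundary polygon: edges of bad triangles not shared by two bad ones
    edges <- do.call(rbind, lapply(tris[bad], function(t) {
      rbind(sort(t[c(1, 2)]), sort(t[c(2, 3)]), sort(t[c(1, 3)]))
    }))
    if (is.null(edges)) next
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tris <- tris[!bad]
    circ <- circ[!bad]
    for (e in seq_len(nrow(boundary))) {
      t_new <- c(boundary[e, 1], boundary[e, 2], i)
      cc <- circumcircle(P[t_new[1], ], P[t_new[2], ], P[t_new[3], ])
      if (is.null(cc)) next
      tris[[length(tris) + 1]] <- t_new
      circ[[length(circ) + 1]] <- cc
    }
  }
  keep <- vapply(tris, function(t) all(t <= n), TRUE)
  out <- do.call(rbind, tris[keep])
  if (is.null(out) || nrow(out) == 0) {
    stop("interpolation error: no valid triangulation (points collinear?)")
  }
  out
}

# Interpolate scattered (x, y, z) onto the grid defined by xi (length nx)
# and yi (length ny). Returns an nx x ny matrix (rows follow xi).
interp_scattered <- function(x, y, z, xi, yi) {
  stopifnot(length(x) == length(y), length(y) == length(z))
  pts <- cbind(x, y)
  # collapse exact duplicate locations to their mean response
  key <- paste(x, y)
  if (anyDuplicated(key)) {
    agg <- tapply(z, key, mean)
    first <- !duplicated(key)
    pts <- pts[first, , drop = FALSE]
    z <- as.numeric(agg[paste(pts[, 1], pts[, 2])])
  }
  cc <- suppressWarnings(stats::cor(pts[, 1], pts[, 2]))
  if (nrow(pts) < 3 || is.na(cc) || abs(cc) > 1 - 1e-12) {
    stop("interpolation error: need at least 3 non-collinear points")
  }
  tri <- delaunay(pts)
  grid <- cbind(rep(xi, times = length(yi)), rep(yi, each = length(xi)))
  zg <- rep(NA_real_, nrow(grid))
  for (t in seq_len(nrow(tri))) {
    a <- pts[tri[t, 1], ]; b <- pts[tri[t, 2], ]; c <- pts[tri[t, 3], ]
    det <- (b[2] - c[2]) * (a[1] - c[1]) + (c[1] - b[1]) * (a[2] - c[2])
    if (abs(det) < 1e-14) next
    todo <- which(is.na(zg))
    if (length(todo) == 0) break
    l1 <- ((b[2] - c[2]) * (grid[todo, 1] - c[1]) +
             (c[1] - b[1]) * (grid[todo, 2] - c[2])) / det
    l2 <- ((c[2] - a[2]) * (grid[todo, 1] - c[1]) +
             (a[1] - c[1]) * (grid[todo, 2] - c[2])) / det
    l3 <- 1 - l1 - l2
    tol <- -1e-9
    inside <- l1 >= tol & l2 >= tol & l3 >= tol
    hit <- todo[inside]
    zg[hit] <- l1[inside] * z[tri[t, 1]] + l2[inside] * z[tri[t, 2]] +
      l3[inside] * z[tri[t, 3]]
  }
  # outside the convex hull: nearest observed value
  miss <- which(is.na(zg))
  if (length(miss) > 0) {
    d2 <- outer(grid[miss, 1], pts[, 1], "-")^2 +
      outer(grid[miss, 2], pts[, 2], "-")^2
    zg[miss] <- z[max.col(-d2, ties.method = "first")]
  }
  matrix(zg, nrow = length(xi), ncol = length(yi))
}
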
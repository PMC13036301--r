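# Planar polygon primitives.
#
# All coordinates are assumed to be in a projected, equal-area system in
# metres (or any consistent planar unit); no CRS handling happens here.
# A ring is an n x 2 numeric matrix of vertices, NOT closed (first vertex is
# not repeated at the end). A polygon is a list of rings, the first being the
# outer boundary and the rest holes (GeoJSON convention). A feature pairs a
# multipolygon (list of polygons) with a property list, and a layer is a list
# of features plus a role label.

#' Signed area of a ring (shoelace formula)
#'
#' Positive for counter-clockwise rings.
#'
#' @param ring n x 2 numeric matrix of vertices, not closed.
#' @return Signed area in squared coordinate units.
#' @keywords internal
ring_area_signed <- function(ring) {
  n <- nrow(ring)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  sum(ring[, 1] * ring[j, 2] - ring[j, 1] * ring[, 2]) / 2
}

#' Area of a polygon (outer ring minus holes)
#' @param poly list of rings, first outer, rest holes.
#' @keywords internal
polygon_area <- function(poly) {
  a <- abs(ring_area_signed(poly[[1]]))
  if (length(poly) > 1) {
    a <- a - sum(vapply(poly[-1], function(r) abs(ring_area_signed(r)), 0))
  }
  max(a, 0)
}

#' Total area of a polygon layer
#'
#' @param layer A `polygon_layer` object.
#' @return Sum of feature areas (holes subtracted) in squared coordinate
#'   units.
#' @export
layer_area <- function(layer) {
  sum(vapply(layer$features, function(f) {
    sum(vapply(f$geometry, polygon_area, 0))
  }, 0))
}

# Even-odd (ray casting) point-in-ring test. Boundary points may fall either
# side; callers needing a deterministic boundary rule must handle ties.
point_in_ring <- function(x, y, ring) {
  n <- nrow(ring)
  xs <- ring[, 1]; ys <- ring[, 2]
  j <- c(n, seq_len(n - 1))
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((ys[i] > y) != (ys[j[i]] > y)) {
      xint <- xs[i] + (y - ys[i]) / (ys[j[i]] - ys[i]) * (xs[j[i]] - xs[i])
      if (x < xint) inside <- !inside
    }
  }
  inside
}

# Even-odd over all rings of a polygon: inside the outer ring and outside an
# even number of holes.
point_in_polygon <- function(x, y, poly) {
  hits <- vapply(poly, function(r) point_in_ring(x, y, r), FALSE)
  sum(hits) %% 2 == 1
}

#' Test whether a point lies inside any feature of a layer
#' @param layer A `polygon_layer`.
#' @param x,y Point coordinates.
#' @return `TRUE` if the point is inside at least one feature.
#' @export
point_in_layer <- function(layer, x, y) {
  for (f in layer$features) {
    for (poly in f$geometry) {
      if (point_in_polygon(x, y, poly)) return(TRUE)
    }
  }
  FALSE
}

# Index of the first feature whose geometry contains the point, or NA.
first_containing_feature <- function(layer, x, y) {
  for (i in seq_along(layer$features)) {
    for (poly in layer$features[[i]]$geometry) {
      if (point_in_polygon(x, y, poly)) return(i)
    }
  }
  NA_integer_
}

# Sutherland-Hodgman clipping of an arbitrary simple subject ring against a
# CONVEX clip ring. Returns a ring (possibly with 0 rows). The clip ring is
# reoriented counter-clockwise internally.
clip_ring_convex <- function(subject, clip) {
  if (ring_area_signed(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0) break
    a <- clip[i, ]
    b <- clip[if (i == nc) 1 else i + 1, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    # signed distance (>= 0 means inside the half-plane left of a->b)
    d <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])
    n <- nrow(out)
    jn <- c(2:n, 1)[seq_len(n)]
    if (n == 1) jn <- 1
    res <- vector("list", 2L * n)
    k <- 0L
    for (v in seq_len(n)) {
      w <- if (v == n) 1L else v + 1L
      cur_in <- d[v] >= 0
      nxt_in <- d[w] >= 0
      if (cur_in) {
        k <- k + 1L; res[[k]] <- out[v, ]
      }
      if (xor(cur_in, nxt_in)) {
        t <- d[v] / (d[v] - d[w])
        k <- k + 1L
        res[[k]] <- out[v, ] + t * (out[w, ] - out[v, ])
      }
    }
    out <- if (k == 0L) matrix(numeric(0), 0, 2) else do.call(rbind, res[seq_len(k)])
  }
  out
}

# Area of the intersection between a polygon (with holes) and a convex ring.
intersection_area_convex <- function(poly, convex_ring) {
  a <- abs(ring_area_signed(clip_ring_convex(poly[[1]], convex_ring)))
  if (length(poly) > 1) {
    for (h in poly[-1]) {
      a <- a - abs(ring_area_signed(clip_ring_convex(h, convex_ring)))
    }
  }
  max(a, 0)
}

#' Polygonized circle
#'
#' Regular polygon approximating a circle, used for plot location buffers.
#'
#' @param x,y Centre coordinates.
#' @param r Radius (> 0).
#' @param n_segments Number of vertices (default 64).
#' @return An n x 2 ring matrix (counter-clockwise).
#' @export
circle_ring <- function(x, y, r, n_segments = 64L) {
  stopifnot(r > 0, n_segments >= 8)
  th <- seq(0, 2 * pi, length.out = n_segments + 1L)[-(n_segments + 1L)]
  cbind(x + r * cos(th), y + r * sin(th))
}

# --- validity repair ---------------------------------------------------------

# Proper intersection point of segments p1-p2 and p3-p4, or NULL. Touching at
# endpoints is not counted (adjacent ring edges always share one).
segment_intersection <- function(p1, p2, p3, p4) {
  d1 <- p2 - p1; d2 <- p4 - p3
  denom <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(denom) < 1e-14) return(NULL)
  dp <- p3 - p1
  t <- (dp[1] * d2[2] - dp[2] * d2[1]) / denom
  u <- (dp[1] * d1[2] - dp[2] * d1[1]) / denom
  eps <- 1e-12
  if (t <= eps || t >= 1 - eps || u <= eps || u >= 1 - eps) return(NULL)
  list(t = t, u = u, pt = p1 + t * d1)
}

ring_self_intersects <- function(ring) {
  n <- nrow(ring)
  if (n < 4) return(FALSE)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i || j == i %% n + 1 || i == j %% n + 1) next
      p <- segment_intersection(ring[i, ], ring[i %% n + 1, ],
                                ring[j, ], ring[j %% n + 1, ])
      if (!is.null(p)) return(TRUE)
    }
  }
  FALSE
}

#' Repair a self-intersecting ring
#'
#' Nodes the ring at proper self-intersections and splits it into simple
#' sub-rings (even-odd semantics): each loop between two visits of an
#' intersection point becomes its own ring, so a bow-tie becomes two
#' triangles whose areas both count. Degenerate slivers (area below `eps`)
#' are dropped.
#'
#' @param ring n x 2 ring matrix.
#' @param eps Minimum |area| for a sub-ring to be kept.
#' @return List of simple rings.
#' @export
repair_ring <- function(ring, eps = 1e-9) {
  if (!ring_self_intersects(ring)) return(list(ring))
  n <- nrow(ring)
  # collect intersection points per edge, parameterized by t along the edge
  extras <- vector("list", n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i %% n + 1 || i == j %% n + 1) next
      p <- segment_intersection(ring[i, ], ring[i %% n + 1, ],
                                ring[j, ], ring[j %% n + 1, ])
      if (!is.null(p)) {
        extras[[i]] <- rbind(extras[[i]], c(p$t, p$pt))
        extras[[j]] <- rbind(extras[[j]], c(p$u, p$pt))
      }
    }
  }
  path <- list()
  for (i in seq_len(n)) {
    path[[length(path) + 1L]] <- ring[i, ]
    ex <- extras[[i]]
    if (!is.null(ex)) {
      ex <- ex[order(ex[, 1]), , drop = FALSE]
      for (r in seq_len(nrow(ex))) path[[length(path) + 1L]] <- ex[r, 2:3]
    }
  }
  pts <- do.call(rbind, path)
  key <- paste(signif(pts[, 1], 12), signif(pts[, 2], 12))
  rings <- list()
  stack_keys <- character(0)
  stack_idx <- integer(0)
  keep <- integer(0)
  for (i in seq_len(nrow(pts))) {
    hit <- match(key[i], stack_keys)
    if (!is.na(hit)) {
      sub <- keep[stack_idx[hit]:length(keep)]
      if (length(sub) >= 3) {
        cand <- pts[sub, , drop = FALSE]
        if (abs(ring_area_signed(cand)) > eps) rings[[length(rings) + 1L]] <- cand
      }
      keep <- keep[seq_len(stack_idx[hit] - 1L)]
      stack_keys <- stack_keys[seq_len(hit - 1L)]
      stack_idx <- stack_idx[seq_len(hit - 1L)]
      # the shared vertex stays once in the remaining path
      keep <- c(keep, i)
      stack_keys <- c(stack_keys, key[i])
      stack_idx <- c(stack_idx, length(keep))
    } else {
      keep <- c(keep, i)
      stack_keys <- c(stack_keys, key[i])
      stack_idx <- c(stack_idx, length(keep))
    }
  }
  if (length(keep) >= 3) {
    cand <- pts[keep, , drop = FALSE]
    if (abs(ring_area_signed(cand)) > eps) rings[[length(rings) + 1L]] <- cand
  }
  if (length(rings) == 0) list(ring) else rings
}

# --- layer construction and GeoJSON I/O --------------------------------------

#' Construct a polygon layer
#'
#' @param features List of features, each `list(geometry = <list of
#'   polygons>, properties = <named list>)`.
#' @param role `"PROTECTED"` or `"REGION"`.
#' @return A `polygon_layer` object.
#' @export
polygon_layer <- function(features, role = c("PROTECTED", "REGION")) {
  role <- match.arg(role)
  structure(list(features = features, role = role), class = "polygon_layer")
}

#' @export
print.polygon_layer <- function(x, ...) {
  cat(sprintf("<polygon_layer role=%s features=%d area=%.6g>\n",
              x$role, length(x$features), layer_area(x)))
  invisible(x)
}

#' Rectangle ring
#'
#' Convenience constructor for axis-aligned rectangular rings
#' (counter-clockwise), the building block of synthetic landscapes and test
#' layers.
#'
#' @param xmin,ymin,xmax,ymax Rectangle bounds.
#' @return A 4 x 2 ring matrix.
#' @export
rect_ring <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

#' Read a polygon layer from GeoJSON
#'
#' Accepts an RFC 7946 FeatureCollection of Polygon/MultiPolygon features.
#' Non-polygonal features are rejected (counted in the `rejected` attribute).
#' Self-intersecting rings are repaired by even-odd re-noding
#' ([repair_ring()]); repaired feature indices are recorded in the
#' `repaired` attribute.
#'
#' @param path Path to a GeoJSON file.
#' @param role Layer role, `"PROTECTED"` or `"REGION"`.
#' @return A `polygon_layer` with attributes `rejected` (count) and
#'   `repaired` (feature indices).
#' @export
read_polygon_layer <- function(path, role = c("PROTECTED", "REGION")) {
  role <- match.arg(role)
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection")
  }
  feats <- list()
  rejected <- 0L
  repaired <- integer(0)
  parse_ring <- function(coords) {
    m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    # drop closing vertex
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    m
  }
  for (f in gj$features) {
    g <- f$geometry
    if (is.null(g$type) || !(g$type %in% c("Polygon", "MultiPolygon"))) {
      rejected <- rejected + 1L
      next
    }
    polys <- if (g$type == "Polygon") list(g$coordinates) else g$coordinates
    geom <- list()
    was_repaired <- FALSE
    for (p in polys) {
      rings <- lapply(p, parse_ring)
      fixed <- list()
      for (ri in seq_along(rings)) {
        r <- rings[[ri]]
        if (ring_self_intersects(r)) {
          was_repaired <- TRUE
          parts <- repair_ring(r)
          if (ri == 1L) {
            # each part becomes its own outer ring (even-odd repair)
            for (pp in parts) geom[[length(geom) + 1L]] <- list(pp)
          } else {
            fixed <- c(fixed, parts)
          }
        } else if (ri == 1L) {
          geom[[length(geom) + 1L]] <- list(r)
        } else {
          fixed <- c(fixed, list(r))
        }
      }
      # attach holes to the last outer pushed for this polygon
      if (length(fixed) > 0 && length(geom) > 0) {
        geom[[length(geom)]] <- c(geom[[length(geom)]], fixed)
      }
    }
    props <- if (is.null(f$properties)) list() else f$properties
    feats[[length(feats) + 1L]] <- list(geometry = geom, properties = props)
    if (was_repaired) repaired <- c(repaired, length(feats))
  }
  if (length(feats) == 0L) warning("empty polygon layer: ", path)
  out <- polygon_layer(feats, role)
  attr(out, "rejected") <- rejected
  attr(out, "repaired") <- repaired
  out
}

#' Write a polygon layer to GeoJSON
#'
#' @param layer A `polygon_layer`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_polygon_layer <- function(layer, path) {
  close_ring <- function(r) {
    r <- rbind(r, r[1, ])
    lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
  }
  feats <- lapply(layer$features, function(f) {
    mp <- lapply(f$geometry, function(poly) lapply(poly, close_ring))
    geometry <- if (length(mp) == 1L) {
      list(type = "Polygon", coordinates = mp[[1]])
    } else {
      list(type = "MultiPolygon", coordinates = mp)
    }
    props <- f$properties
    if (length(props) == 0) props <- stats::setNames(list(), character(0))
    list(type = "Feature", properties = props, geometry = geometry)
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}
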
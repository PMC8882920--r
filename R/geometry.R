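# Planar geometry for vowel-space measurement. The hull is implemented from
# first principles (Andrew's monotone chain) so it is a tested component in
# its own right rather than a call into a geometry library.

#' Perceptual distance between two vowels in Bark space
#'
#' Euclidean distance between two (B1, B2) points, the perceptual distance
#' used for all dispersion statistics.
#'
#' @param p,q Numeric length-2 vectors `(b1, b2)` in Bark.
#' @return Non-negative distance in Bark.
#' @examples
#' perceptual_distance(c(3, 10), c(6, 14)) # 5
#' @export
perceptual_distance <- function(p, q) {
  vd_check_numeric(p, "p"); vd_check_numeric(q, "q")
  if (length(p) != 2 || length(q) != 2) {
    vd_abort("perceptual_distance: points must have length 2.",
             "voweldisp_domain_error")
  }
  sqrt(sum((p - q)^2))
}

# All n(n-1)/2 pairwise Bark distances as a numeric vector.
pairwise_distances <- function(b1, b2) {
  as.numeric(stats::dist(cbind(b1, b2)))
}

# Cross product z-component of (b - a) x (c - a); > 0 means c lies to the
# left of a -> b (counter-clockwise turn).
cross2 <- function(a, b, c) {
  (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
}

#' Convex hull of a planar point set (monotone chain)
#'
#' Computes the convex hull of the deduplicated points, returned as a tibble
#' of vertices in counter-clockwise order with the first vertex not repeated.
#' Degenerate inputs (fewer than 3 distinct points, or all points collinear)
#' raise an error: a zero-area hull would make dispersion-per-unit-area
#' statistics undefined.
#'
#' @param b1,b2 Numeric coordinate vectors (Bark).
#' @return Tibble with columns `b1`, `b2`: the hull vertices, CCW.
#' @examples
#' convex_hull(c(0, 1, 1, 0, 0.5), c(0, 0, 1, 1, 0.5)) # the unit square
#' @export
convex_hull <- function(b1, b2) {
  vd_check_numeric(b1, "b1"); vd_check_numeric(b2, "b2")
  if (length(b1) != length(b2)) {
    vd_abort("convex_hull: coordinate vectors differ in length.",
             "voweldisp_domain_error")
  }
  pts <- unique(cbind(b1, b2))
  if (nrow(pts) < 3) {
    vd_abort("convex_hull: need >= 3 distinct points.",
             "voweldisp_degenerate_error")
  }
  ord <- order(pts[, 1], pts[, 2])
  pts <- pts[ord, , drop = FALSE]
  n <- nrow(pts)
  build <- function(idx) {
    chain <- integer(0)
    for (i in idx) {
      while (length(chain) >= 2 &&
             cross2(pts[chain[length(chain) - 1], ],
                    pts[chain[length(chain)], ], pts[i, ]) <= 0) {
        chain <- chain[-length(chain)]
      }
      chain <- c(chain, i)
    }
    chain
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  hull_idx <- c(lower[-length(lower)], upper[-length(upper)])
  if (length(hull_idx) < 3) {
    vd_abort("convex_hull: all points are collinear (zero-area hull).",
             "voweldisp_degenerate_error")
  }
  out <- tibble::tibble(b1 = pts[hull_idx, 1], b2 = pts[hull_idx, 2])
  class(out) <- c("hull_polygon", class(out))
  out
}

#' Area of a convex polygon (shoelace formula)
#'
#' @param hull A tibble/data frame of vertices with columns `b1`, `b2` in
#'   counter-clockwise order (as returned by [convex_hull()]), or a 2-column
#'   matrix.
#' @return Strictly positive area in Bark squared.
#' @examples
#' polygon_area(convex_hull(c(0, 4, 0), c(0, 0, 3))) # 6
#' @export
polygon_area <- function(hull) {
  if (is.matrix(hull)) hull <- tibble::tibble(b1 = hull[, 1], b2 = hull[, 2])
  vd_require_columns(hull, c("b1", "b2"), "polygon_area")
  x <- hull$b1; y <- hull$b2
  n <- length(x)
  if (n < 3) {
    vd_abort("polygon_area: need >= 3 vertices.", "voweldisp_degenerate_error")
  }
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}
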
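# Shared fixtures and independent oracles, all built in code.

# Canonical cardinal-vowel fixture (Hz). /u/ has the low, close formants of a
# cardinal back rounded vowel, which is what makes it focal.
canonical_vowels <- function() {
  tibble::tibble(
    vowel = c("i", "e", "a", "o", "u"),
    f1 = c(280, 390, 710, 450, 300),
    f2 = c(2250, 2200, 1100, 900, 600))
}

canonical_bark <- function() {
  v <- canonical_vowels()
  v$b1 <- hz_to_bark(v$f1)
  v$b2 <- hz_to_bark(v$f2)
  v
}

# A formant table fixture spanning two systems, as written text.
write_fixture_table <- function(path, extra_rows = NULL) {
  header <- "sample_id\tiso\tfamily\tregion\tvowel\tf1\tf2"
  rows <- c(
    "s1\taaa\tFamA\tEurope\ti\t280\t2250",
    "s1\taaa\tFamA\tEurope\ta\t710\t1100",
    "s1\taaa\tFamA\tEurope\tu\t300\t600",
    "s2\tbbb\tFamB\tAfrica\ti\t300\t2100",
    "s2\tbbb\tFamB\tAfrica\ta\t700\t1200",
    "s2\tbbb\tFamB\tAfrica\to\t450\t900")
  writeLines(c(header, rows, extra_rows), path)
  path
}

# Brute-force hull-vertex oracle: an edge (i, j) is a hull edge iff every
# other point lies weakly on one side of it; hull vertices are the union of
# hull-edge endpoints. Quadratic-cubic, valid for small point sets in
# general position.
oracle_hull_vertices <- function(x, y, tol = 1e-12) {
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  is_vertex <- rep(FALSE, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- vapply(seq_len(n)[-c(i, j)], function(k) {
        (pts[j, 1] - pts[i, 1]) * (pts[k, 2] - pts[i, 2]) -
          (pts[j, 2] - pts[i, 2]) * (pts[k, 1] - pts[i, 1])
      }, numeric(1))
      if (all(s >= -tol) || all(s <= tol)) {
        is_vertex[c(i, j)] <- TRUE
      }
    }
  }
  pts[is_vertex, , drop = FALSE]
}

# Vectorized point-in-convex-polygon test for a CCW vertex list: returns a
# logical per (px, py) point.
in_convex_polygon <- function(px, py, hull, tol = 1e-9) {
  n <- nrow(hull)
  j <- c(2:n, 1)
  ok <- rep(TRUE, length(px))
  for (e in seq_len(n)) {
    cr <- (hull$b1[j[e]] - hull$b1[e]) * (py - hull$b2[e]) -
      (hull$b2[j[e]] - hull$b2[e]) * (px - hull$b1[e])
    ok <- ok & (cr >= -tol)
  }
  ok
}

sorted_rows <- function(m) {
  m <- as.matrix(m)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# 4-tip worked contrast fixture: tree ((A:1,B:2):1,(C:3,D:1):2); with
# values A=1, B=3, C=6, D=2, executed by hand through the pruning pass:
#   node AB: contrast (1-3)/sqrt(1+2), value 5/3, stem 1 + 2/3
#   node CD: contrast (6-2)/sqrt(3+1), value 3,   stem 2 + 3/4
#   root:    contrast (5/3 - 3)/sqrt(5/3 + 11/4)
pic_fixture <- function() {
  list(
    tree = read_newick("((A:1,B:2):1,(C:3,D:1):2);"),
    trait = c(A = 1, B = 3, C = 6, D = 2),
    contrasts = c(AB = -2 / sqrt(3), CD = 2,
                  root = (5 / 3 - 3) / sqrt(5 / 3 + 11 / 4)),
    variances = c(AB = 3, CD = 4, root = 5 / 3 + 11 / 4))
}

# Dense-algebra GLS oracle: explicit inversion, no factorization tricks.
oracle_gls_slope <- function(V, x, y) {
  X <- cbind(1, x)
  Vi <- solve(V)
  as.numeric(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y))[2]
}
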
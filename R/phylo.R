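# Tree handling and phylogenetically independent contrasts. Tree I/O and
# topology surgery go through ape; the contrast recursion is implemented
# here so its algebra is a tested component of the package.

#' Read a rooted phylogeny from Newick text
#'
#' Wraps [ape::read.tree()] with the validation this package's comparative
#' methods require: a rooted tree, unique tip labels, and branch lengths on
#' every edge (non-negative).
#'
#' @param source Path to a Newick file, or a Newick string.
#' @return An [ape] `phylo` object.
#' @export
read_newick <- function(source) {
  tree <- if (length(source) == 1 && file.exists(source)) {
    ape::read.tree(source)
  } else {
    ape::read.tree(text = source)
  }
  if (is.null(tree)) {
    vd_abort("read_newick: could not parse Newick input.",
             "voweldisp_config_error")
  }
  validate_phylogeny(tree)
  tree
}

#' Write a phylogeny as Newick text
#'
#' @param tree A `phylo` object.
#' @param file Output path; `NULL` returns the Newick string.
#' @return The file path (invisibly) or the Newick string.
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(file)) {
    ape::write.tree(tree)
  } else {
    ape::write.tree(tree, file = file)
    invisible(file)
  }
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) {
    vd_abort("expected an ape 'phylo' tree.", "voweldisp_config_error")
  }
  if (anyDuplicated(tree$tip.label)) {
    dups <- unique(tree$tip.label[duplicated(tree$tip.label)])
    vd_abort(sprintf("duplicate tip label(s): %s",
                     paste(dups, collapse = ", ")),
             "voweldisp_config_error")
  }
  if (is.null(tree$edge.length)) {
    vd_abort("tree has no branch lengths.", "voweldisp_config_error")
  }
  if (any(tree$edge.length < 0)) {
    vd_abort("negative branch length(s).", "voweldisp_config_error")
  }
  # a basal polytomy reads as "unrooted" to ape but is handled by
  # resolve_polytomies(); only a binary unrooted tree is truly ambiguous
  if (!ape::is.rooted(tree) && ape::is.binary(tree)) {
    vd_abort("tree must be rooted.", "voweldisp_config_error")
  }
  invisible(tree)
}

#' Prune a phylogeny to a subset of tips
#'
#' Drops all tips outside `keep`, collapsing the resulting degree-2 internal
#' nodes and summing their branch lengths, so root-to-tip path lengths and
#' pairwise patristic distances among kept tips are preserved.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (>= 2).
#' @return The induced `phylo` subtree.
#' @export
prune_to_taxa <- function(tree, keep) {
  validate_phylogeny(tree)
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown)) {
    vd_abort(sprintf("prune_to_taxa: unknown taxa: %s",
                     paste(unknown, collapse = ", ")),
             "voweldisp_config_error")
  }
  if (length(keep) < 2) {
    vd_abort("prune_to_taxa: keep at least 2 tips.",
             "voweldisp_config_error")
  }
  ape::keep.tip(tree, keep)
}

#' Resolve polytomies into bifurcations
#'
#' Multifurcations are split into arbitrary bifurcations whose new internal
#' branches get a small positive length, `epsilon` times the tree depth, so
#' the contrast recursion (which divides by branch-length sums) stays
#' defined.
#'
#' @param tree A `phylo` object.
#' @param epsilon New-branch length as a fraction of tree depth.
#' @return A fully bifurcating `phylo`.
#' @export
resolve_polytomies <- function(tree, epsilon = 1e-8) {
  validate_phylogeny(tree)
  if (ape::is.binary(tree)) return(tree)
  depth <- max(ape::node.depth.edgelength(tree))
  out <- ape::multi2di(tree, random = FALSE)
  out$edge.length[out$edge.length == 0] <- epsilon * depth
  out
}

#' Phylogenetically independent contrasts (Felsenstein pruning)
#'
#' Standardized contrasts for one continuous trait on a fully bifurcating
#' tree. At each internal node the contrast is the difference between the
#' two daughter values divided by the square root of the summed (adjusted)
#' branch lengths; the node's own value is the branch-length-weighted average
#' of the daughters, and its stem is lengthened by `v1*v2/(v1+v2)` to carry
#' the estimation uncertainty rootward. Under Brownian motion the resulting
#' n-1 contrasts are independent with unit variance, which removes the
#' shared-ancestry confound (Galton's problem) from trait correlations.
#'
#' @param tree Fully bifurcating `phylo` (see [resolve_polytomies()]).
#' @param trait Named numeric vector (names = tip labels) or data frame with
#'   columns `tip` and a single trait column.
#' @return Object of class `vowel_contrasts`: a tibble with `node` (internal
#'   node id), `contrast` (standardized), and `variance` (the sum of adjusted
#'   daughter branch lengths).
#' @export
independent_contrasts <- function(tree, trait) {
  validate_phylogeny(tree)
  if (!ape::is.binary(tree)) {
    vd_abort(paste0("independent_contrasts: tree has polytomies; resolve ",
                    "them first with resolve_polytomies()."),
             "voweldisp_config_error")
  }
  x <- as_tip_vector(trait, tree)
  n <- length(tree$tip.label)
  n_nodes <- n + tree$Nnode
  val <- numeric(n_nodes); val[seq_len(n)] <- x[tree$tip.label]
  edge_len <- numeric(n_nodes) # adjusted length of each node's stem
  edge_len[tree$edge[, 2]] <- tree$edge.length
  contrast <- rep(NA_real_, n_nodes)
  cvar <- rep(NA_real_, n_nodes)
  ord <- ape::reorder.phylo(tree, "postorder")
  # walk edges two at a time: postorder guarantees children precede parents
  edges <- ord$edge
  lens <- ord$edge.length
  i <- 1
  while (i < nrow(edges)) {
    parent <- edges[i, 1]
    stopifnot(edges[i + 1, 1] == parent)
    c1 <- edges[i, 2]; c2 <- edges[i + 1, 2]
    v1 <- edge_len[c1]; v2 <- edge_len[c2]
    if (v1 + v2 <= 0) {
      vd_abort(sprintf(
        "independent_contrasts: zero combined branch length at node %d.",
        parent), "voweldisp_degenerate_error")
    }
    contrast[parent] <- (val[c1] - val[c2]) / sqrt(v1 + v2)
    cvar[parent] <- v1 + v2
    val[parent] <- (val[c1] / v1 + val[c2] / v2) / (1 / v1 + 1 / v2)
    edge_len[parent] <- edge_len[parent] + v1 * v2 / (v1 + v2)
    i <- i + 2
  }
  nodes <- (n + 1):n_nodes
  out <- tibble::tibble(node = nodes, contrast = contrast[nodes],
                        variance = cvar[nodes])
  class(out) <- c("vowel_contrasts", class(out))
  out
}

# Coerce a trait argument to a named vector covering all tips of `tree`.
as_tip_vector <- function(trait, tree) {
  if (is.data.frame(trait)) {
    vd_require_columns(trait, "tip", "trait table")
    value_col <- setdiff(names(trait), "tip")
    if (length(value_col) != 1) {
      vd_abort("trait table must have exactly one value column besides `tip`.",
               "voweldisp_config_error")
    }
    x <- stats::setNames(trait[[value_col]], trait$tip)
  } else {
    x <- trait
  }
  if (is.null(names(x))) {
    vd_abort("trait must be named by tip label.", "voweldisp_config_error")
  }
  missing <- setdiff(tree$tip.label, names(x))
  if (length(missing)) {
    vd_abort(sprintf("trait missing for tip(s): %s",
                     paste(missing, collapse = ", ")),
             "voweldisp_config_error")
  }
  if (any(!is.finite(x[tree$tip.label]))) {
    vd_abort("trait contains missing or non-finite values.",
             "voweldisp_domain_error")
  }
  x[tree$tip.label]
}

#' Correlation of two sets of independent contrasts
#'
#' Contrasts have an arbitrary sign and zero expectation, so their
#' correlation is computed through the origin (no intercept):
#' \eqn{\rho = \sum c_x c_y / \sqrt{\sum c_x^2 \sum c_y^2}}.
#'
#' @param cx,cy `vowel_contrasts` from the same tree (same node order).
#' @return The through-origin correlation, a number in `[-1, 1]`.
#' @export
contrast_correlation <- function(cx, cy) {
  if (!identical(cx$node, cy$node)) {
    vd_abort("contrast_correlation: contrast sets from different trees.",
             "voweldisp_config_error")
  }
  sx <- sum(cx$contrast^2); sy <- sum(cy$contrast^2)
  if (sx == 0 || sy == 0) {
    vd_abort("contrast_correlation: all contrasts zero for one trait.",
             "voweldisp_domain_error")
  }
  sum(cx$contrast * cy$contrast) / sqrt(sx * sy)
}

#' Expected trait covariance among tips under BM or OU
#'
#' Brownian motion: `V[i, j]` is the shared root-to-MRCA path length (the
#' classic BM covariance, units of branch length). Ornstein-Uhlenbeck
#' (Martins-Hansen correlation form): `C[i, j] = exp(-alpha * d[i, j])` with
#' `d` the patristic distance, i.e. the stationary-variance-normalized
#' correlation structure (unit diagonal); the overall scale is left to the
#' fitting routine, which estimates it by maximum likelihood.
#'
#' @param tree A `phylo` object.
#' @param process `"BM"` or `"OU"`.
#' @param alpha OU attraction strength (> 0); required for `"OU"`.
#' @return Symmetric positive-definite matrix with tip labels as dimnames.
#' @export
phylo_vcv <- function(tree, process = c("BM", "OU"), alpha = NULL) {
  process <- match.arg(process)
  validate_phylogeny(tree)
  if (process == "BM") {
    V <- ape::vcv(tree)
  } else {
    if (is.null(alpha) || !is.finite(alpha) || alpha <= 0) {
      vd_abort("phylo_vcv: OU requires alpha > 0.", "voweldisp_domain_error")
    }
    if (!ape::is.ultrametric(tree, tol = 1e-6)) {
      warning("phylo_vcv: OU stationary correlation assumes an ",
              "ultrametric tree; results are approximate.", call. = FALSE)
    }
    D <- stats::cophenetic(tree)
    V <- exp(-alpha * D)
  }
  ev_min <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 1e-12 * max(diag(V))) {
    vd_abort(sprintf(
      "phylo_vcv: covariance numerically singular (min eigenvalue %.3e).",
      ev_min), "voweldisp_degenerate_error")
  }
  V
}
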
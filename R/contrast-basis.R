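#' Compositional closure
#'
#' Rescales a vector of strictly positive parts so that its components sum
#' to one, i.e. projects it onto the unit simplex. Only the relative
#' information in `x` is retained; `closure()` is idempotent.
#'
#' @param x Numeric vector of strictly positive, finite parts.
#' @return Numeric vector of proportions summing to 1 (names preserved).
#' @examples
#' closure(c(1, 1, 1, 1))
#' closure(c(2, 6))
#' @export
closure <- function(x) {
  if (!is.numeric(x) || length(x) < 1L) {
    stop("`x` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("all components of `x` must be finite and strictly positive",
         call. = FALSE)
  }
  x / sum(x)
}

#' Sign matrix of a rooted binary tree
#'
#' Encodes the sequential binary partition induced by a rooted, strictly
#' binary tree as an (n-1) x n matrix over \{-1, 0, +1\}: row i corresponds
#' to internal node i (deterministic preorder from the root), and entry
#' (i, j) is -1 if leaf j belongs to the left subclade of node i, +1 if it
#' belongs to the right subclade, and 0 if it does not descend from node i.
#' "Left" is the first child in Newick order, "right" the second.
#'
#' @param tree A rooted, strictly binary `ape::phylo` tree with uniquely
#'   named leaves.
#' @param leaf_order Character vector fixing the column order; must be a
#'   permutation of the tip labels. Defaults to the tree's tip label order.
#' @return Integer matrix of dimension (n-1) x n with `leaf_order` as
#'   column names and internal node row names `node1`, `node2`, ...
#' @export
sign_matrix_from_tree <- function(tree, leaf_order = NULL) {
  if (!inherits(tree, "phylo")) {
    stop("`tree` must be an `ape::phylo` object", call. = FALSE)
  }
  n <- length(tree$tip.label)
  if (n < 2L) stop("tree must have at least 2 leaves", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf names in tree", call. = FALSE)
  }
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  if (!ape::is.binary(tree)) {
    stop("tree must be strictly binary; resolve multifurcations upstream",
         call. = FALSE)
  }
  if (is.null(leaf_order)) {
    leaf_order <- tree$tip.label
  } else {
    if (!setequal(leaf_order, tree$tip.label) ||
        length(leaf_order) != n) {
      stop("`leaf_order` must be a permutation of the tree's tip labels",
           call. = FALSE)
    }
  }
  tree <- ape::reorder.phylo(tree, "cladewise")
  edge <- tree$edge
  # cladewise edge order is a depth-first preorder; internal nodes appear
  # as parents in that same order, root first
  internal <- unique(edge[, 1L])
  stopifnot(length(internal) == n - 1L)

  # tips descending from every node, by one pass over edges in postorder
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  for (k in rev(seq_len(nrow(edge)))) {
    p <- edge[k, 1L]; ch <- edge[k, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }

  col_of <- match(tree$tip.label, leaf_order)
  phi <- matrix(0L, nrow = n - 1L, ncol = n,
                dimnames = list(paste0("node", seq_len(n - 1L)), leaf_order))
  for (r in seq_along(internal)) {
    children <- edge[edge[, 1L] == internal[r], 2L]
    stopifnot(length(children) == 2L)
    phi[r, col_of[desc[[children[1L]]]]] <- -1L
    phi[r, col_of[desc[[children[2L]]]]] <- +1L
  }
  phi
}

#' Contrast matrix from a sign matrix
#'
#' Rescales the rows of a sign matrix into the orthonormal, zero-row-sum
#' contrast matrix that defines an ILR basis. For row i with n- negative
#' and n+ positive entries and k = sqrt(n- n+ / (n- + n+)), negative
#' entries become -k/n-, positive entries +k/n+, zeros stay zero.
#'
#' @param phi Sign matrix as produced by [sign_matrix_from_tree()].
#' @return Real matrix of the same dimension; every row sums to zero and
#'   has unit Euclidean norm, and distinct rows are orthogonal.
#' @export
contrast_from_sign <- function(phi) {
  if (!is.matrix(phi) || !all(phi %in% c(-1, 0, 1))) {
    stop("`phi` must be a matrix over {-1, 0, +1}", call. = FALSE)
  }
  psi <- matrix(0, nrow = nrow(phi), ncol = ncol(phi),
                dimnames = dimnames(phi))
  for (i in seq_len(nrow(phi))) {
    neg <- phi[i, ] < 0
    pos <- phi[i, ] > 0
    n_neg <- sum(neg); n_pos <- sum(pos)
    if (n_neg == 0L || n_pos == 0L) {
      stop("sign-matrix row ", i, " lacks entries of both signs",
           call. = FALSE)
    }
    k <- sqrt(n_neg * n_pos / (n_neg + n_pos))
    psi[i, neg] <- -k / n_neg
    psi[i, pos] <- +k / n_pos
  }
  psi
}

#' Build an ILR contrast basis from a phylogeny
#'
#' Bundles a rooted binary tree with its sign and contrast matrices. The
#' basis fixes the template (column) order used throughout the package.
#'
#' @inheritParams sign_matrix_from_tree
#' @return An object of class `contrast_basis`: a list with elements
#'   `tree`, `leaf_order`, `sign` and `contrast`.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),C);")
#' basis <- contrast_basis(tr)
#' basis$contrast
#' @export
contrast_basis <- function(tree, leaf_order = NULL) {
  phi <- sign_matrix_from_tree(tree, leaf_order)
  structure(
    list(tree = tree,
         leaf_order = colnames(phi),
         sign = phi,
         contrast = contrast_from_sign(phi)),
    class = "contrast_basis"
  )
}

#' @export
print.contrast_basis <- function(x, ...) {
  cat("<contrast_basis> ", length(x$leaf_order), " templates, ",
      nrow(x$contrast), " balances\n", sep = "")
  invisible(x)
}

n_templates <- function(basis) length(basis$leaf_order)

check_basis <- function(basis) {
  if (!inherits(basis, "contrast_basis")) {
    stop("expected a `contrast_basis` object", call. = FALSE)
  }
  basis
}

#' Isometric log-ratio transform
#'
#' Maps an n-part vector of strictly positive parts to its n-1 balance
#' coordinates, b = log(x) Psi^T, in the basis defined by the tree. The
#' transform is invariant to positive rescaling of `x`, so per-sample
#' library-size factors cancel exactly.
#'
#' @param x Strictly positive numeric vector of length n, or an n x m
#'   matrix with templates in rows (ordered as `basis$leaf_order`).
#' @param basis A [contrast_basis()].
#' @return Balance vector of length n-1, or an (n-1) x m matrix.
#' @export
ilr <- function(x, basis) {
  check_basis(basis)
  psi <- basis$contrast
  if (is.matrix(x)) {
    if (nrow(x) != ncol(psi)) {
      stop("`x` has ", nrow(x), " rows but the basis expects ",
           ncol(psi), " templates", call. = FALSE)
    }
    if (any(x == 0)) {
      stop("`x` contains zeros; run zero_replace() first", call. = FALSE)
    }
    if (any(!is.finite(x)) || any(x < 0)) {
      stop("`x` must be finite and strictly positive", call. = FALSE)
    }
    b <- psi %*% log(x)
    rownames(b) <- rownames(psi)
    return(b)
  }
  if (length(x) != ncol(psi)) {
    stop("`x` has length ", length(x), " but the basis expects ",
         ncol(psi), " templates", call. = FALSE)
  }
  if (any(x == 0)) {
    stop("`x` contains zeros; run zero_replace() first", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("`x` must be finite and strictly positive", call. = FALSE)
  }
  drop(psi %*% log(x))
}

#' Inverse isometric log-ratio transform
#'
#' Maps balances back onto the simplex: x = closure(exp(b Psi)). Up to
#' closure this inverts [ilr()].
#'
#' @param b Numeric balance vector of length n-1, or an (n-1) x m matrix
#'   of balances in columns.
#' @param basis A [contrast_basis()].
#' @return Composition vector of length n (sums to 1), or an n x m matrix
#'   of compositions in columns.
#' @export
ilr_inverse <- function(b, basis) {
  check_basis(basis)
  psi <- basis$contrast
  if (is.matrix(b)) {
    if (nrow(b) != nrow(psi)) {
      stop("`b` has ", nrow(b), " rows but the basis has ",
           nrow(psi), " balances", call. = FALSE)
    }
    if (any(!is.finite(b))) stop("`b` must be finite", call. = FALSE)
    e <- exp(crossprod(psi, b))          # n x m
    rownames(e) <- colnames(psi)
    return(sweep(e, 2L, colSums(e), "/"))
  }
  if (length(b) != nrow(psi)) {
    stop("`b` has length ", length(b), " but the basis has ",
         nrow(psi), " balances", call. = FALSE)
  }
  if (any(!is.finite(b))) stop("`b` must be finite", call. = FALSE)
  x <- exp(drop(crossprod(psi, b)))
  names(x) <- colnames(psi)
  x / sum(x)
}

#' Aitchison distance between two compositions
#'
#' Euclidean distance between the balance vectors of two compositions.
#' Independent of the particular binary tree used, since all orthonormal
#' ILR bases are rotations of one another.
#'
#' @param x,y Strictly positive vectors of equal length n.
#' @param basis A [contrast_basis()] on n templates.
#' @return Non-negative scalar.
#' @export
aitchison_distance <- function(x, y, basis) {
  sqrt(sum((ilr(x, basis) - ilr(y, basis))^2))
}
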
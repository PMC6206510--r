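#' Escoufier's RV coefficient between two variable blocks
#'
#' A scalar 0–1 measure of association between two groups of variables,
#' `RV = tr(Sxy Syx) / sqrt(tr(Sxx^2) tr(Syy^2))` on column-centered blocks.
#' It generalizes the squared Pearson correlation (to which it reduces for
#' two single columns) and is invariant to orthogonal rotation of either
#' block — which is what makes it suitable for comparing 3D landmark blocks.
#'
#' @param X,Y Numeric matrices with the same number of rows (subjects).
#' @return RV coefficient in `[0, 1]`.
#' @export
rv_coefficient <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  assert_that(nrow(X) == nrow(Y), "X and Y must have the same number of rows")
  assert_that(nrow(X) >= 3, "RV needs at least 3 observations")
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  sxx <- sum(crossprod(Xc)^2)
  syy <- sum(crossprod(Yc)^2)
  assert_that(sxx > 0 && syy > 0, "RV undefined for a zero-variance block")
  sxy <- sum(crossprod(Xc, Yc)^2)
  min(max(sxy / sqrt(sxx * syy), 0), 1)
}

#' Landmark-by-landmark RV similarity matrix
#'
#' Entry `(i, j)` is the RV coefficient between the two `n x 3` coordinate
#' blocks of landmarks `i` and `j`, computed over subjects. All blocks are
#' evaluated from one pooled cross-product matrix, so the full `L x L`
#' matrix costs a single `(3L)^2` covariance.
#'
#' @param shapes `n x L x 3` array (typically symmetrized, aligned, adjusted
#'   configurations, pooled over cohorts) or an `n x 3L` flattened matrix.
#' @return Symmetric `L x L` matrix with unit diagonal, entries in `[0, 1]`.
#' @export
landmark_rv_matrix <- function(shapes) {
  flat <- if (length(dim(shapes)) == 3) flatten_configs(shapes) else as.matrix(shapes)
  n <- nrow(flat); L <- ncol(flat) / 3
  assert_that(L == round(L), "flattened shapes must have 3L columns")
  assert_that(n >= 3, "need at least 3 subjects")
  Xc <- sweep(flat, 2, colMeans(flat))
  C <- crossprod(Xc)
  # block sums of squares: N[i,j] = ||C_block(i,j)||_F^2
  B <- kronecker(diag(L), rep(1, 3))        # 3L x L block indicator
  N <- t(B) %*% (C * C) %*% B
  d <- diag(N)
  bad <- which(d <= 0)
  assert_that(length(bad) == 0,
              paste("zero-variance landmark block at index:", paste(bad, collapse = ", ")))
  RV <- N / sqrt(outer(d, d))
  RV <- (RV + t(RV)) / 2
  RV[RV > 1] <- 1; RV[RV < 0] <- 0
  diag(RV) <- 1
  RV
}

#' Bisect an index set by the Fiedler vector of its similarity graph
#'
#' Builds the symmetric normalized graph Laplacian of the similarity
#' submatrix and splits by the sign of the Fiedler (second-smallest
#' eigenvalue) eigenvector. The eigenvector sign is fixed so the first index
#' has a non-negative loading; exact zeros join the smaller side. If the
#' Fiedler vector is (numerically) constant the graph is split by connected
#' components instead. An optional `min_size` rebalances the split by moving
#' the indices with the smallest |Fiedler| loadings — i.e. those least
#' committed to either side — until both sides are large enough.
#'
#' @param similarity Symmetric similarity matrix (restricted to the index
#'   set being split).
#' @param min_size Minimum size of each side (default 1).
#' @return List of two integer vectors (positions into the supplied
#'   submatrix), both non-empty.
#' @export
spectral_bisect <- function(similarity, min_size = 1L) {
  S <- as.matrix(similarity)
  m <- nrow(S)
  assert_that(m >= 2, "need at least two indices to bisect")
  assert_that(max(abs(S - t(S))) < 1e-8, "similarity matrix must be symmetric")
  assert_that(2L * min_size <= m, "min_size too large for this index set")
  if (m == 2) return(list(1L, 2L))
  d <- rowSums(S)
  d[d <= 0] <- 1e-12
  Dm <- 1 / sqrt(d)
  Lsym <- diag(m) - (Dm * S) %*% diag(Dm)   # I - D^-1/2 S D^-1/2
  Lsym <- (Lsym + t(Lsym)) / 2
  ev <- eigen(Lsym, symmetric = TRUE)
  f <- ev$vectors[, m - 1L]                 # second-smallest eigenvalue
  f <- f * Dm                               # back to the random-walk embedding
  if (diff(range(f)) < 1e-10) {
    # degenerate: split by connected components
    g <- igraph::graph_from_adjacency_matrix(S > 1e-12, mode = "undirected", diag = FALSE)
    comp <- igraph::components(g)$membership
    if (max(comp) < 2) {                    # fully connected but constant: index split
      half <- floor(m / 2)
      return(list(seq_len(half), (half + 1L):m))
    }
    side1 <- which(comp == 1)
    return(rebalance_split(side1, setdiff(seq_len(m), side1), abs(f), min_size))
  }
  j <- which(abs(f) > 0)[1]
  if (f[j] < 0) f <- -f                     # sign convention
  pos <- which(f > 0); neg <- which(f < 0); zer <- which(f == 0)
  if (length(zer)) {
    if (length(pos) <= length(neg)) pos <- c(pos, zer) else neg <- c(neg, zer)
  }
  if (length(pos) == 0 || length(neg) == 0) {
    ord <- order(f)
    half <- floor(m / 2)
    neg <- ord[seq_len(half)]; pos <- ord[(half + 1L):m]
  }
  rebalance_split(sort(pos), sort(neg), abs(f), min_size)
}

# move least-committed indices (smallest weight) to satisfy min_size
rebalance_split <- function(a, b, weight, min_size) {
  while (length(a) < min_size) {
    mv <- b[which.min(weight[b])]
    b <- setdiff(b, mv); a <- c(a, mv)
  }
  while (length(b) < min_size) {
    mv <- a[which.min(weight[a])]
    a <- setdiff(a, mv); b <- c(b, mv)
  }
  list(sort(as.integer(a)), sort(as.integer(b)))
}

#' Hierarchical spectral segmentation into facial modules
#'
#' Recursively bisects the full landmark set with [spectral_bisect()] on the
#' RV similarity matrix, producing a strictly bifurcating module tree:
#' `2^(depth+1) - 1` modules, with the full face at level 0 and `2^k`
#' modules at level `k` (63 modules at the default depth 5). An optional
#' k-nearest-neighbour adjacency mask on the template enforces spatial
#' contiguity of the similarity graph.
#'
#' @param shapes `n x L x 3` array of (adjusted, aligned) shapes, or a
#'   precomputed similarity matrix from [landmark_rv_matrix()].
#' @param depth Tree depth (>= 0); requires `L >= min_leaf * 2^depth`.
#' @param min_leaf Minimum landmarks per module at the deepest level
#'   (default 1; pipelines that phenotype every module use 3, the smallest
#'   set a per-module Procrustes fit can align).
#' @param adjacency Optional `L x L` 0/1 matrix multiplying the similarity
#'   (e.g. from [knn_adjacency()]); default none.
#' @return A `module_tree` tibble (`module_id`, `level`, `parent_id`,
#'   `landmarks` list-column) with heap-numbered ids (children of `i` are
#'   `2i`, `2i+1`).
#' @export
hierarchical_segment <- function(shapes, depth = 5, min_leaf = 1L, adjacency = NULL) {
  S <- if (is.matrix(shapes) && nrow(shapes) == ncol(shapes) &&
           isTRUE(all.equal(unname(shapes), unname(t(shapes)), tolerance = 1e-6))) {
    shapes
  } else landmark_rv_matrix(shapes)
  L <- nrow(S)
  assert_that(depth >= 0 && depth == round(depth), "depth must be a non-negative integer")
  assert_that(L >= min_leaf * 2^depth,
              sprintf("L = %d cannot support depth %d with min_leaf %d; lower the depth",
                      L, depth, min_leaf))
  if (!is.null(adjacency)) {
    assert_that(all(dim(adjacency) == c(L, L)), "adjacency must be L x L")
    S <- S * ((adjacency + t(adjacency)) > 0)
    diag(S) <- 1
  }
  modules <- list(list(id = 1L, level = 0L, parent = NA_integer_, lmk = seq_len(L)))
  for (lev in seq_len(depth)) {
    need <- as.integer(min_leaf * 2^(depth - lev))  # children must stay splittable
    prev <- Filter(function(m) m$level == lev - 1L, modules)
    for (m in prev) {
      sub <- S[m$lmk, m$lmk, drop = FALSE]
      halves <- spectral_bisect(sub, min_size = need)
      modules <- c(modules,
                   list(list(id = 2L * m$id, level = lev, parent = m$id,
                             lmk = m$lmk[halves[[1]]]),
                        list(id = 2L * m$id + 1L, level = lev, parent = m$id,
                             lmk = m$lmk[halves[[2]]])))
    }
  }
  if (depth == 0 && is.null(modules[[1]]$parent)) modules[[1]]$parent <- NA_integer_
  new_module_tree(modules)
}

#' k-nearest-neighbour adjacency mask on a template
#'
#' @param template A `template_face` (or an `L x 3` coordinate matrix).
#' @param k Number of nearest neighbours.
#' @return Symmetric 0/1 `L x L` matrix (mutual-or adjacency, unit diagonal).
#' @export
knn_adjacency <- function(template, k = 8) {
  coords <- if (inherits(template, "template_face")) template$coordinates else as.matrix(template)
  L <- nrow(coords)
  D <- as.matrix(dist(coords))
  A <- matrix(0L, L, L)
  for (i in seq_len(L)) {
    nn <- order(D[i, ])[2:(k + 1)]
    A[i, nn] <- 1L
  }
  A <- ((A + t(A)) > 0) * 1L
  diag(A) <- 1L
  A
}

#' Validate the structural invariants of a module tree
#'
#' Checks that level 0 is the full landmark set, each level has `2^k`
#' modules partitioning the landmarks, children partition their parent, and
#' no module is empty.
#'
#' @param tree A `module_tree`.
#' @param L Total landmark count.
#' @return `TRUE` invisibly; aborts with a message otherwise.
#' @export
validate_module_tree <- function(tree, L) {
  depth <- max(tree$level)
  assert_that(nrow(tree) == 2^(depth + 1) - 1, "module count must be 2^(depth+1)-1")
  for (lev in 0:depth) {
    rows <- tree[tree$level == lev, ]
    assert_that(nrow(rows) == 2^lev, sprintf("level %d must have %d modules", lev, 2^lev))
    all_l <- sort(unlist(rows$landmarks))
    assert_that(identical(all_l, seq_len(L)),
                sprintf("level %d does not partition the landmark set", lev))
  }
  for (i in seq_len(nrow(tree))) {
    m <- tree[i, ]
    assert_that(length(m$landmarks[[1]]) > 0, "empty module")
    if (m$level > 0) {
      parent <- tree[tree$module_id == m$parent_id, ]
      assert_that(all(m$landmarks[[1]] %in% parent$landmarks[[1]]),
                  "child landmarks not inside parent")
    }
  }
  invisible(TRUE)
}
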
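#' Deterministic symmetric template face
#'
#' Builds a bilaterally symmetric, face-like layout of `L` landmarks on a
#' half-ellipsoid (semi-axes 65 x 90 x 50 mm; width, height, depth), with a
#' mirror-pairing map across the `x = 0` midsagittal plane and seven named
#' anatomical landmarks (glabella, nasion, subnasale, prosthion, stomion,
#' gnathion on the midline; paired zygia at the widest point). It stands in
#' for a symmetric dense-correspondence mask: every simulated subject shares
#' this homologous indexing.
#'
#' @param L Number of landmarks; even, at least 16. Six landmarks sit on the
#'   midline, the rest form `(L - 6) / 2` mirror pairs.
#' @return An object of class `template_face`: a list with `coordinates`
#'   (`L x 3` matrix, mm), `mirror_map` (integer involution over landmark
#'   indices), and `named_landmarks` (named integer vector).
#' @examples
#' tf <- generate_template_face(64)
#' tf$named_landmarks
#' @export
generate_template_face <- function(L) {
  assert_that(is.numeric(L) && length(L) == 1 && L == round(L),
              "L must be a single integer")
  L <- as.integer(L)
  assert_that(L >= 16, sprintf("L = %d is too small: need L >= 16 (6 midline landmarks + mirror pairs)", L))
  assert_that(L %% 2 == 0, sprintf("L = %d must be even so that non-midline landmarks pair across the midline", L))

  a <- 65; b <- 90; cc <- 50  # ellipsoid semi-axes, mm

  # 6 midline landmarks, ordered superior -> inferior on the facial profile
  mid_y <- c(55, 35, -20, -35, -50, -80)
  mid <- cbind(x = 0, y = mid_y, z = cc * sqrt(pmax(0, 1 - (mid_y / b)^2)))
  mid_names <- c("glabella", "nasion", "subnasale", "prosthion", "stomion", "gnathion")

  n_pairs <- (L - 6L) %/% 2L
  # first pair: zygia at the widest lateral extent
  alpha <- 1.35; beta <- 0.12
  zyg <- c(a * sin(alpha), b * cos(alpha) * sin(beta), cc * cos(alpha) * cos(beta))

  # remaining pairs: low-discrepancy (Halton base 2/3) angular grid, right half
  halton <- function(n, base) {
    vapply(seq_len(n), function(i) {
      f <- 1; r <- 0
      while (i > 0) { f <- f / base; r <- r + f * (i %% base); i <- i %/% base }
      r
    }, numeric(1))
  }
  m <- n_pairs - 1L
  pts <- NULL
  if (m > 0) {
    al <- 0.15 + 1.18 * halton(m, 2)
    be <- -1.10 + 1.90 * halton(m, 3)
    pts <- cbind(a * sin(al), b * cos(al) * sin(be), cc * cos(al) * cos(be))
  }
  right <- rbind(zyg, pts)

  coords <- matrix(0, L, 3)
  coords[1:6, ] <- mid
  mirror_map <- seq_len(L)
  for (p in seq_len(n_pairs)) {
    i_l <- 6L + 2L * p - 1L   # +x side ("left" by subject convention)
    i_r <- 6L + 2L * p
    coords[i_l, ] <- right[p, ]
    coords[i_r, ] <- right[p, ] * c(-1, 1, 1)
    mirror_map[i_l] <- i_r
    mirror_map[i_r] <- i_l
  }
  colnames(coords) <- c("x", "y", "z")

  named <- c(glabella = 1L, nasion = 2L, subnasale = 3L, prosthion = 4L,
             stomion = 5L, gnathion = 6L, zygion_l = 7L, zygion_r = 8L)

  structure(list(coordinates = coords, mirror_map = as.integer(mirror_map),
                 named_landmarks = named),
            class = "template_face")
}

#' @export
print.template_face <- function(x, ...) {
  cat(sprintf("<template_face> %d landmarks (6 midline, %d mirror pairs)\n",
              nrow(x$coordinates), (nrow(x$coordinates) - 6L) %/% 2L))
  cat("named landmarks:", paste(names(x$named_landmarks), collapse = ", "), "\n")
  invisible(x)
}

#' Geometric module hierarchy of a template face
#'
#' Recursive balanced bisection of the template landmarks in the
#' symmetry-aware coordinate space `(|x|, y, z)`: at each node the landmark
#' set splits at the median along its highest-variance axis, keeping mirror
#' pairs together. This yields a strictly bifurcating tree of `2^(depth+1)-1`
#' modules used to *define* simulation targets (e.g. a mandibular module);
#' the data-driven segmentation of observed shapes is
#' [hierarchical_segment()].
#'
#' @param template A `template_face`.
#' @param depth Tree depth; depth 5 gives 63 modules.
#' @param min_leaf Minimum landmarks per module at the deepest level
#'   (default 3, the smallest per-module Procrustes-alignable set); requires
#'   `L >= min_leaf * 2^depth`.
#' @return A `module_tree` tibble with columns `module_id`, `level`,
#'   `parent_id`, `landmarks` (list-column of integer vectors).
#' @export
template_module_tree <- function(template, depth = 5, min_leaf = 3L) {
  stopifnot(inherits(template, "template_face"))
  L <- nrow(template$coordinates)
  assert_that(depth >= 0 && depth == round(depth), "depth must be a non-negative integer")
  assert_that(L >= min_leaf * 2^depth,
              sprintf("L = %d cannot support depth %d with min_leaf %d", L, depth, min_leaf))
  xyz <- template$coordinates
  sym <- cbind(abs(xyz[, 1]), xyz[, 2], xyz[, 3])

  split_node <- function(idx, need) {
    m <- length(idx)
    v <- apply(sym[idx, , drop = FALSE], 2, var)
    ax <- which.max(v)
    vals <- sym[idx, ax]
    ord <- order(vals, idx)
    k <- floor(m / 2)
    # prefer a boundary that does not separate tied values (mirror pairs
    # share |x|, y, z), searching outward from the middle within bounds
    lo <- need; hi <- m - need
    best <- NA_integer_
    for (off in 0:m) {
      for (cand in unique(c(k - off, k + off))) {
        if (cand >= lo && cand <= hi && cand >= 1 && cand < m &&
            vals[ord[cand]] != vals[ord[cand + 1]]) { best <- cand; break }
      }
      if (!is.na(best)) break
    }
    if (is.na(best)) best <- min(max(k, lo), hi)  # tie-separating fallback
    list(sort(idx[ord[seq_len(best)]]), sort(idx[ord[(best + 1):m]]))
  }

  modules <- list(list(id = 1L, level = 0L, parent = NA_integer_, lmk = seq_len(L)))
  for (lev in seq_len(depth)) {
    need <- as.integer(min_leaf * 2^(depth - lev))
    prev <- Filter(function(m) m$level == lev - 1L, modules)
    for (m in prev) {
      ch <- split_node(m$lmk, need)
      modules <- c(modules,
                   list(list(id = 2L * m$id, level = lev, parent = m$id, lmk = ch[[1]]),
                        list(id = 2L * m$id + 1L, level = lev, parent = m$id, lmk = ch[[2]])))
    }
  }
  new_module_tree(modules)
}

# shared constructor for module trees (heap-numbered ids)
new_module_tree <- function(modules) {
  tb <- tibble::tibble(
    module_id = vapply(modules, function(m) m$id, integer(1)),
    level = vapply(modules, function(m) m$level, integer(1)),
    parent_id = vapply(modules, function(m) m$parent, integer(1)),
    landmarks = lapply(modules, function(m) as.integer(m$lmk))
  )
  tb <- dplyr::arrange(tb, .data$module_id)
  class(tb) <- c("module_tree", class(tb))
  tb
}

#' Find the module containing a named landmark at a given level
#'
#' @param tree A `module_tree`.
#' @param template A `template_face` (for name resolution), or an integer
#'   landmark index.
#' @param name Landmark name, e.g. `"gnathion"` for the mandibular region.
#' @param level Tree level at which to report the module.
#' @return The `module_id` of the module at `level` containing the landmark.
#' @export
module_containing <- function(tree, template, name = "gnathion", level = 2) {
  idx <- if (is.numeric(template)) as.integer(template) else {
    assert_that(name %in% names(template$named_landmarks),
                sprintf("unknown landmark name '%s'", name))
    template$named_landmarks[[name]]
  }
  rows <- dplyr::filter(tree, .data$level == !!level)
  hit <- vapply(rows$landmarks, function(l) idx %in% l, logical(1))
  assert_that(any(hit), "landmark not found at the requested level")
  rows$module_id[which(hit)[1]]
}
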
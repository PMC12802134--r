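#' Symmetric pairwise distance matrices
#'
#' Lightweight validated container for feature-by-feature distances: the
#' matrix must be symmetric, non-negative, finite, with a zero diagonal and
#' unique labels.
#'
#' @param D square numeric matrix with dimnames.
#' @return object of class `dist_matrix` (a labelled matrix).
#' @export
dist_matrix <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (is.null(rownames(D))) stop("distance matrix needs labels")
  if (anyDuplicated(rownames(D))) stop("duplicate labels")
  if (any(!is.finite(D))) stop("non-finite distances")
  if (any(D < 0)) stop("negative distances")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix not symmetric")
  if (max(abs(diag(D))) > 1e-8) stop("nonzero diagonal")
  D <- (D + t(D)) / 2
  diag(D) <- 0
  colnames(D) <- rownames(D)
  class(D) <- c("dist_matrix", "matrix", "array")
  D
}

#' Patristic distances between tree leaves
#'
#' Sum of branch lengths along the path between each pair of leaves of a
#' phylogenetic tree. Requested taxa missing from the tree are dropped with
#' a warning.
#'
#' @param tree an [ape::phylo] object or path to a Newick file.
#' @param taxa_ids leaf labels to keep (default: all leaves).
#' @return a [dist_matrix()] over the matched leaves.
#' @export
patristic_distances <- function(tree, taxa_ids = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object or file")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (is.null(taxa_ids)) taxa_ids <- tree$tip.label
  matched <- intersect(taxa_ids, tree$tip.label)
  if (length(matched) < length(taxa_ids)) {
    warning("dropping ", length(taxa_ids) - length(matched),
            " taxa absent from the tree")
  }
  if (length(matched) < 2) stop("fewer than 2 taxa matched tree leaves")
  D <- ape::cophenetic.phylo(tree)[matched, matched]
  dist_matrix(D)
}

#' Principal coordinate (classical MDS) embedding
#'
#' Double-centres the squared distance matrix, eigendecomposes, and scales
#' eigenvectors by the square root of their (positive) eigenvalues. Axes
#' with non-positive eigenvalues (arising from non-Euclidean inputs such as
#' Tanimoto distances) are discarded. Each axis' sign is fixed by making its
#' first nonzero coordinate positive, so embeddings are reproducible.
#'
#' @param D a [dist_matrix()].
#' @param dims number of axes requested; reduced with a warning if it
#'   exceeds the number of positive eigenvalues.
#' @return list of class `pcoa_embedding` with `coords` (N x D matrix),
#'   `eigenvalues` (all N, decreasing), `labels`.
#' @export
pcoa_embed <- function(D, dims) {
  n <- nrow(D)
  if (dims < 1) stop("dims must be >= 1")
  if (dims > n - 1) stop("dims must be <= N - 1")
  cm <- stats::cmdscale(stats::as.dist(unclass(D)), k = n - 1, eig = TRUE)
  eig <- cm$eig
  npos <- sum(eig > 1e-10)
  if (npos == 0) stop("no positive eigenvalue; degenerate distance matrix")
  if (dims > npos) {
    warning("requested ", dims, " dims but only ", npos,
            " positive eigenvalues; reducing")
    dims <- npos
  }
  coords <- cm$points[, seq_len(dims), drop = FALSE]
  for (j in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, j]) > 1e-12)
    if (length(nz) > 0 && coords[nz[1], j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(D)
  structure(list(coords = coords, eigenvalues = eig, labels = rownames(D)),
            class = "pcoa_embedding")
}

#' @export
print.pcoa_embedding <- function(x, ...) {
  cat(sprintf("<pcoa_embedding> %d features in %d dimensions\n",
              nrow(x$coords), ncol(x$coords)))
  invisible(x)
}

embedding_distances <- function(emb) {
  as.matrix(stats::dist(emb$coords))
}

#' Select embedding dimensionality by distance-distribution agreement
#'
#' Searches ascending dimensions for the smallest embedding whose pairwise
#' distance distribution is not significantly different from the input
#' distances (two-sample Kolmogorov-Smirnov test on all upper-triangle
#' pairs, significance level `alpha`). Used for phylogenetic distances.
#'
#' @param D a [dist_matrix()].
#' @param alpha KS significance level (default 0.05).
#' @return the selected dimension (N-1 with a warning if no dimension
#'   passes).
#' @export
select_dims_taxa <- function(D, alpha = 0.05) {
  n <- nrow(D)
  if (n == 2) return(1L)
  if (n < 2) stop("need at least 2 features")
  upper_in <- unclass(D)[upper.tri(D)]
  full <- pcoa_embed(D, n - 1)
  npos <- sum(full$eigenvalues > 1e-10)
  for (d in seq_len(npos)) {
    coords <- full$coords[, seq_len(d), drop = FALSE]
    upper_out <- stats::dist(coords)
    p <- suppressWarnings(stats::ks.test(upper_in, as.numeric(upper_out)))$p.value
    if (p >= alpha) return(d)
  }
  warning("no dimension up to ", n - 1,
          " matched the input distance distribution; using ", n - 1)
  as.integer(n - 1)
}

#' Select embedding dimensionality by explained variance
#'
#' Smallest number of PCoA axes whose eigenvalues account for at least
#' `var_frac` of the total positive eigenvalue mass. Used for
#' fingerprint-derived metabolite distances.
#'
#' @param D a [dist_matrix()].
#' @param var_frac target variance fraction (default 0.95).
#' @return the selected dimension.
#' @export
select_dims_metab <- function(D, var_frac = 0.95) {
  n <- nrow(D)
  if (n < 2) stop("need at least 2 features")
  full <- pcoa_embed(D, 1)
  pos <- full$eigenvalues[full$eigenvalues > 1e-10]
  if (length(pos) == 0) stop("no positive eigenvalue")
  cum <- cumsum(pos) / sum(pos)
  as.integer(which(cum >= var_frac - 1e-12)[1])
}

#' Calibrate the Log-Normal radius prior from biological groupings
#'
#' For each group (chemical sub-class for metabolites, taxonomic family for
#' taxa) with at least three members, computes the median within-group
#' pairwise Euclidean distance in the embedding, h_c. The prior on detector
#' radii is LogNormal with location `median_c(h_c)` and squared scale
#' `variance_c(h_c)` (sample variance, n-1 denominator), interpreted as the
#' mean and variance of log(radius). Set `natural_scale = TRUE` to instead
#' match those moments on the natural scale of the radius.
#'
#' @param emb a [pcoa_embed()] result.
#' @param groups named character vector or two-column data frame
#'   (`feature_id`, `group`) mapping features to group labels; `NULL`
#'   falls back to k-means pseudo-groups in the embedding with a warning.
#' @param min_group_size groups below this size are excluded (default 3).
#' @param natural_scale interpret (location, scale^2) as natural-scale
#'   moments rather than log-scale parameters.
#' @return list of class `lognormal_prior` with `log_location`,
#'   `log_scale2`, `source_groups_used`.
#' @export
calibrate_radius_prior <- function(emb, groups, min_group_size = 3,
                                   natural_scale = FALSE) {
  if (is.null(groups)) {
    warning("no grouping supplied; calibrating from embedding clusters")
    groups <- pseudo_groups(emb)
  }
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups[[2]]),
                              as.character(groups[[1]]))
  }
  groups <- groups[names(groups) %in% emb$labels]
  h <- c()
  for (g in unique(groups)) {
    members <- names(groups)[groups == g]
    if (length(members) < min_group_size) next
    d <- stats::dist(emb$coords[members, , drop = FALSE])
    h <- c(h, stats::median(as.numeric(d)))
  }
  if (length(h) == 0) {
    stop("no group with at least ", min_group_size, " embedded members")
  }
  loc <- stats::median(h)
  s2 <- if (length(h) >= 2) stats::var(h) else 0
  if (s2 <= 0) {
    warning("degenerate group medians; flooring radius-prior variance at 1e-4")
    s2 <- 1e-4
  }
  if (natural_scale) {
    # moment-match: mean m, variance v on the natural scale
    m <- loc
    if (m <= 0) stop("natural-scale location must be positive")
    log_scale2 <- log(1 + s2 / m^2)
    log_location <- log(m) - log_scale2 / 2
  } else {
    log_location <- loc
    log_scale2 <- s2
  }
  structure(list(log_location = log_location, log_scale2 = log_scale2,
                 source_groups_used = length(h)),
            class = "lognormal_prior")
}

#' @export
print.lognormal_prior <- function(x, ...) {
  cat(sprintf("<lognormal_prior> log-location %.4g, log-scale^2 %.4g (%d groups)\n",
              x$log_location, x$log_scale2, x$source_groups_used))
  invisible(x)
}
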
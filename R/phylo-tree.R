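#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou–Nei agglomeration (via [ape::nj()]) with two conventions
#' enforced at this surface: the input must be a symmetric matrix with zero
#' diagonal and at least three taxa, and negative branch-length estimates —
#' a known artifact of NJ on noisy distances — are clamped to zero with a
#' warning. On an additive (tree-like) metric the generating topology and
#' branch lengths are recovered exactly.
#'
#' @param D symmetric numeric distance matrix (substitutions/site) with taxa
#'   as dimnames.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!is.matrix(D) || !is.numeric(D) || nrow(D) != ncol(D))
    stop("`D` must be a square numeric matrix", call. = FALSE)
  if (nrow(D) < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-8 || any(abs(diag(D)) > 1e-12))
    stop("`D` must be symmetric with a zero diagonal", call. = FALSE)
  tree <- ape::nj(stats::as.dist(D))
  neg <- tree$edge.length < 0
  if (any(neg)) {
    warning(sum(neg), " negative NJ branch length(s) clamped to 0")
    tree$edge.length[neg] <- 0
  }
  tree
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Builds the point-estimate tree from the full alignment, then resamples
#' alignment columns with replacement `B` times, rebuilds a tree per
#' replicate, and scores each internal bipartition of the point tree by the
#' percentage of replicate trees containing it. Replicates producing a
#' saturated distance are skipped with a message; if more than 20% are
#' skipped the run aborts.
#'
#' @inheritParams aa_distance_matrix
#' @param B number of bootstrap replicates (default 100).
#' @param seed integer seed controlling the column resampling.
#' @return The point-estimate `phylo` tree with internal-node labels holding
#'   percentage supports (root label empty).
#' @export
bootstrap_support <- function(alignment, model = c("poisson", "p", "gamma"),
                              alpha = 1, B = 100L, seed = 1L) {
  model <- match.arg(model)
  m <- alignment_matrix(alignment)
  if (B < 1L) stop("need B >= 1", call. = FALSE)
  point <- neighbor_joining(aa_distance_matrix(m, model, alpha))
  reps <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(B), function(b) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      tryCatch(
        suppressWarnings(
          neighbor_joining(aa_distance_matrix(m[, cols, drop = FALSE],
                                              model, alpha))),
        error = function(e) NULL)
    })
  })
  ok <- !vapply(reps, is.null, logical(1))
  if (mean(!ok) > 0.2)
    stop("more than 20% of bootstrap replicates were saturated",
         call. = FALSE)
  if (any(!ok))
    message(sum(!ok), " saturated bootstrap replicate(s) skipped")
  reps <- reps[ok]
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / length(reps), 1)
  point$node.label <- as.character(support)
  point$node.label[1L] <- ""        # root of the unrooted representation
  point
}

#' Root an unrooted tree on the branch subtending an outgroup
#'
#' The root is placed at the midpoint of the branch separating the outgroup
#' tips from the rest, so patristic distances are preserved. The outgroup
#' must form one side of a bipartition of the unrooted tree.
#'
#' @param tree an unrooted `phylo` tree.
#' @param outgroup character vector of tip labels.
#' @return A rooted `phylo` tree.
#' @export
root_by_outgroup <- function(tree, outgroup) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo", call. = FALSE)
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing))
    stop("outgroup tips not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  ingroup <- setdiff(tree$tip.label, outgroup)
  if (length(ingroup) == 0L)
    stop("outgroup cannot contain every tip", call. = FALSE)
  # outgroup forms a split iff it is a clade once the tree is rooted at any
  # ingroup tip
  probe <- ape::root(tree, outgroup = ingroup[1L], resolve.root = TRUE)
  if (length(outgroup) > 1L &&
      !ape::is.monophyletic(probe, outgroup))
    stop("outgroup {", paste(outgroup, collapse = ", "),
         "} is not monophyletic in the unrooted tree: no bipartition ",
         "separates it from the remaining tips", call. = FALSE)
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  root <- length(rooted$tip.label) + 1L
  e <- which(rooted$edge[, 1L] == root)
  if (length(e) == 2L) {
    half <- sum(rooted$edge.length[e]) / 2
    rooted$edge.length[e] <- half    # midpoint of the split branch
  }
  rooted
}
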
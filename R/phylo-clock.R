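calibration_time <- function(calib, a, b) {
  hit <- (calib$taxonA == a & calib$taxonB == b) |
         (calib$taxonA == b & calib$taxonB == a)
  if (!any(hit)) return(NA_real_)
  calib$time_mya[which(hit)[1L]]
}

check_calibration <- function(calib) {
  need <- c("taxonA", "taxonB", "time_mya")
  if (!is.data.frame(calib) || !all(need %in% names(calib)))
    stop("calibration table needs columns taxonA, taxonB, time_mya",
         call. = FALSE)
  if (any(calib$time_mya <= 0))
    stop("divergence times must be positive", call. = FALSE)
  calib
}

#' Per-clade molecular-clock rates and root age of a paralog duplication
#'
#' For each named clade, the substitution rate is the mean over calibrated
#' in-clade tip pairs of `patristic(i, j) / (2 * t_ij)` — each lineage
#' accumulates for `t_ij` million years — and the root (duplication) age is
#' the clade's mean root-to-tip patristic distance divided by that rate.
#' With two paralog clades this yields two independent datings of the same
#' duplication node; the reported interval is their `[min, max]` range, not
#' an average.
#'
#' @param tree rooted `phylo` tree with branch lengths in
#'   substitutions/site, e.g. from [root_by_outgroup()].
#' @param calib calibration table: data frame with columns `taxonA`,
#'   `taxonB`, `time_mya` (species divergence times, million years).
#' @param clades named list of tip-label vectors, one per clade.
#' @return An object of class `clock_fit` with per-clade `rate`
#'   (substitutions/site/Mya), per-clade `root_age_mya`, and
#'   `interval_mya = c(min, max)` over clades.
#' @export
fit_clock <- function(tree, calib, clades) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo", call. = FALSE)
  if (!ape::is.rooted(tree)) stop("`tree` must be rooted", call. = FALSE)
  check_calibration(calib)
  if (!is.list(clades) || is.null(names(clades)) || length(clades) == 0L)
    stop("`clades` must be a non-empty named list of tip sets",
         call. = FALSE)
  pat <- ape::cophenetic.phylo(tree)
  depth <- ape::node.depth.edgelength(tree)  # root-to-node distances
  tips <- tree$tip.label
  rate <- age <- setNames(numeric(length(clades)), names(clades))
  for (cl in names(clades)) {
    members <- clades[[cl]]
    miss <- setdiff(members, tips)
    if (length(miss))
      stop("clade ", cl, " lists unknown tips: ",
           paste(miss, collapse = ", "), call. = FALSE)
    rr <- c()
    if (length(members) >= 2L) {
      prs <- utils::combn(members, 2L)
      for (k in seq_len(ncol(prs))) {
        t_ij <- calibration_time(calib, prs[1L, k], prs[2L, k])
        if (!is.na(t_ij))
          rr <- c(rr, pat[prs[1L, k], prs[2L, k]] / (2 * t_ij))
      }
    }
    if (length(rr) == 0L)
      stop("clade ", cl, " has no calibrated in-clade tip pair",
           call. = FALSE)
    r <- mean(rr)
    if (r <= 0) stop("clade ", cl, " has zero substitution rate",
                     call. = FALSE)
    rate[cl] <- r
    age[cl] <- mean(depth[match(members, tips)]) / r
  }
  structure(list(rate = rate, root_age_mya = age,
                 interval_mya = c(min(age), max(age))),
            class = "clock_fit")
}

#' @export
print.clock_fit <- function(x, ...) {
  cat("<clock_fit>\n")
  for (cl in names(x$rate))
    cat(sprintf("  %s: rate %.4g subs/site/Mya, root age %.1f Mya\n",
                cl, x$rate[cl], x$root_age_mya[cl]))
  cat(sprintf("  root-age interval: %.1f - %.1f Mya\n",
              x$interval_mya[1L], x$interval_mya[2L]))
  invisible(x)
}

#' Divergence-time vs substitution-distance profile of a focal taxon
#'
#' Machine-readable form of a calibrated rate plot: for every non-focal tip,
#' the pair (calibrated divergence time from the focal taxon, amino-acid
#' distance to the focal taxon), sorted by time, with the slope of each
#' consecutive segment in substitutions/site/Mya. The series starts at the
#' implicit origin (0, 0), so a single comparison taxon yields one segment.
#' Because the distance to the focal taxon spans both diverging lineages,
#' a clock with per-lineage rate `r` produces constant slopes of `2 r`.
#'
#' @param tree rooted `phylo` with branch lengths in substitutions/site.
#' @param focal tip label of the reference taxon.
#' @param calib calibration table (see [fit_clock()]) providing a divergence
#'   time between the focal taxon and every other tip.
#' @param alignment optional alignment (see [aa_distance_matrix()]); when
#'   given, distances to the focal taxon are direct pairwise corrected
#'   distances rather than patristic distances from the tree.
#' @inheritParams aa_distance_matrix
#' @return Data frame with columns `taxon`, `time_mya`, `distance`, `slope`
#'   (slope of the segment ending at that row).
#' @export
rate_profile <- function(tree, focal, calib, alignment = NULL,
                         model = c("poisson", "p", "gamma"), alpha = 1) {
  model <- match.arg(model)
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo", call. = FALSE)
  if (!focal %in% tree$tip.label)
    stop("focal taxon not in tree: ", focal, call. = FALSE)
  check_calibration(calib)
  others <- setdiff(tree$tip.label, focal)
  times <- vapply(others, function(tp) calibration_time(calib, focal, tp),
                  numeric(1))
  if (anyNA(times))
    stop("missing calibration to focal for: ",
         paste(others[is.na(times)], collapse = ", "), call. = FALSE)
  if (is.null(alignment)) {
    pat <- ape::cophenetic.phylo(tree)
    dist <- pat[focal, others]
  } else {
    D <- aa_distance_matrix(alignment, model, alpha)
    miss <- setdiff(c(focal, others), rownames(D))
    if (length(miss))
      stop("alignment lacks taxa: ", paste(miss, collapse = ", "),
           call. = FALSE)
    dist <- D[focal, others]
  }
  ord <- order(times, others)
  out <- data.frame(taxon = others[ord], time_mya = times[ord],
                    distance = unname(dist[ord]), stringsAsFactors = FALSE)
  # slope of the segment reaching each point, taken from the last point at
  # a strictly earlier time (tips tied in time share a reference point);
  # the series starts at the implicit origin (0, 0)
  out$slope <- vapply(seq_len(nrow(out)), function(i) {
    j <- which(out$time_mya < out$time_mya[i])
    if (length(j)) {
      j <- max(j)
      (out$distance[i] - out$distance[j]) /
        (out$time_mya[i] - out$time_mya[j])
    } else out$distance[i] / out$time_mya[i]
  }, numeric(1))
  rownames(out) <- NULL
  out
}
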
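AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

truth_record <- function(generator, seed, params, manifest = character()) {
  list(generator = generator, seed = as.integer(seed), params = params,
       manifest = manifest)
}

random_protein <- function(len) paste(sample(AA20, len, TRUE), collapse = "")

#' Synthetic proteome with planted ITAM-probe motifs
#'
#' Decoy proteins are drawn uniformly over the 20 residues and rejection
#' sampled until they contain no match to the probe; planted proteins carry
#' exactly one match at a known position with a known spacer. The analytic
#' per-start match probability (about `7 * 4 / 160000` for the default
#' probe) keeps rejections rare.
#'
#' @param n_planted,n_decoys number of motif-bearing and motif-free
#'   proteins.
#' @param length_range inclusive range of protein lengths.
#' @param pattern the [motif_pattern()] to plant and to reject against.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @return List with `sequences` (named character vector; planted proteins
#'   are named `PLT...`, decoys `DCY...`) and `truth` (generator name,
#'   seed, parameters including per-plant `start` and `spacer`).
#' @export
gen_proteome <- function(n_planted = 50L, n_decoys = 500L,
                         length_range = c(200L, 400L),
                         pattern = motif_pattern(), seed = 1L) {
  stopifnot(length_range[1L] >= 20L, length_range[2L] >= length_range[1L])
  withr::with_seed(as.integer(seed), {
    decoys <- character(n_decoys)
    if (n_decoys > 0L) for (i in seq_len(n_decoys)) {
      repeat {
        s <- random_protein(sample(length_range[1L]:length_range[2L], 1L))
        if (nrow(scan_sequence(s, pattern)) == 0L) break
      }
      decoys[i] <- s
    }
    plants <- character(n_planted)
    plant_start <- plant_spacer <- integer(n_planted)
    if (n_planted > 0L) for (i in seq_len(n_planted)) {
      repeat {
        len <- sample(length_range[1L]:length_range[2L], 1L)
        sp <- sample(pattern$spacer_min:pattern$spacer_max, 1L)
        mlen <- 8L + sp
        st <- sample(seq_len(len - mlen + 1L), 1L)
        ch <- strsplit(random_protein(len), "")[[1]]
        ch[st] <- pattern$anchor1
        ch[st + 3L] <- sample(pattern$tail1, 1L)
        ch[st + 4L + sp] <- pattern$anchor2
        ch[st + 7L + sp] <- sample(pattern$tail2, 1L)
        s <- paste(ch, collapse = "")
        h <- scan_sequence(s, pattern)
        if (nrow(h) == 1L && h$start == st && h$spacer == sp) break
      }
      plants[i] <- s
      plant_start[i] <- st
      plant_spacer[i] <- sp
    }
    seqs <- c(setNames(plants, sprintf("PLT%03d", seq_len(n_planted))),
              setNames(decoys, sprintf("DCY%03d", seq_len(n_decoys))))
    list(sequences = seqs,
         truth = truth_record("gen_proteome", seed,
                              list(n_planted = n_planted,
                                   n_decoys = n_decoys,
                                   length_range = length_range,
                                   start = plant_start,
                                   spacer = plant_spacer)))
  })
}

#' Synthetic cross-dataset expression abundances
#'
#' Log-normal abundances with a tunable rank concordance across datasets:
#' each gene has a latent standard-normal score `z`, and dataset `d` draws
#' its score as `rho * z + sqrt(1 - rho^2) * noise`, so `rho = 1` gives
#' identical rank orders and `rho = 0` independent ones. Defaults emulate a
#' panel of seven myeloid RNA-seq samples (two dendritic-cell, four
#' macrophage, one RAW264.7 line) with a wide log-normal abundance spread.
#'
#' @param genes character vector of gene symbols.
#' @param n_datasets number of abundance tables (default 7).
#' @param meanlog,sdlog log-normal parameters of the abundances.
#' @param concordance latent rank correlation `rho` in `[0, 1]`.
#' @param seed integer seed.
#' @return List with `tables` (named list of data frames `gene`,
#'   `abundance`) and `truth` (includes the latent order).
#' @export
gen_expression <- function(genes, n_datasets = 7L, meanlog = 4, sdlog = 2,
                           concordance = 1, seed = 1L) {
  if (sdlog <= 0) stop("`sdlog` must be > 0", call. = FALSE)
  if (concordance < 0 || concordance > 1)
    stop("`concordance` must be in [0, 1]", call. = FALSE)
  nm <- c("bmdc1", "bmdc2", "bmdm1", "bmdm2", "bmdm3", "bmdm4", "raw1")
  nm <- if (n_datasets <= length(nm)) nm[seq_len(n_datasets)] else
    paste0("dataset", seq_len(n_datasets))
  withr::with_seed(as.integer(seed), {
    z <- rnorm(length(genes))
    tables <- setNames(lapply(seq_len(n_datasets), function(d) {
      w <- concordance * z +
        sqrt(1 - concordance^2) * rnorm(length(genes))
      data.frame(gene = genes,
                 abundance = exp(meanlog + sdlog * w),
                 stringsAsFactors = FALSE)
    }), nm)
    list(tables = tables,
         truth = truth_record("gen_expression", seed,
                              list(genes = genes, n_datasets = n_datasets,
                                   meanlog = meanlog, sdlog = sdlog,
                                   concordance = concordance,
                                   latent_order = order(-z))))
  })
}

#' Symmetric two-clade ultrametric tree
#'
#' Convenience topology for clock-dating recoveries: two four-tip clades
#' joined at a root of the given age, each clade's crown at half the root
#' age, with staggered internal splits. Branch lengths are in million
#' years.
#'
#' @param root_age_mya age of the root (default 800 Mya).
#' @param labels optional 8 tip labels (default `A1..A4`, `B1..B4`).
#' @return An ultrametric rooted `phylo` tree.
#' @export
two_clade_tree <- function(root_age_mya = 800, labels = NULL) {
  if (is.null(labels)) labels <- c(paste0("A", 1:4), paste0("B", 1:4))
  stopifnot(length(labels) == 8L)
  a <- root_age_mya
  nwk <- sprintf(
    "(((%s:%g,%s:%g):%g,(%s:%g,%s:%g):%g):%g,((%s:%g,%s:%g):%g,(%s:%g,%s:%g):%g):%g);",
    labels[1], a / 8, labels[2], a / 8, a * 3 / 8,
    labels[3], a / 4, labels[4], a / 4, a / 4, a / 2,
    labels[5], a / 8, labels[6], a / 8, a * 3 / 8,
    labels[7], a / 4, labels[8], a / 4, a / 4, a / 2)
  ape::read.tree(text = nwk)
}

#' Calibration table from a time-scaled tree
#'
#' Tip-pair divergence times (half the patristic distance on a tree whose
#' branch lengths are million years), in the format [fit_clock()] expects.
#'
#' @param tree ultrametric `phylo` with branch lengths in Mya.
#' @return Data frame `taxonA`, `taxonB`, `time_mya`.
#' @export
calibration_from_tree <- function(tree) {
  pat <- ape::cophenetic.phylo(tree)
  prs <- utils::combn(tree$tip.label, 2L)
  data.frame(taxonA = prs[1L, ], taxonB = prs[2L, ],
             time_mya = pat[cbind(prs[1L, ], prs[2L, ])] / 2,
             stringsAsFactors = FALSE)
}

#' Evolve a protein alignment along a time-scaled tree
#'
#' Poisson (20-state symmetric) substitution process: the root sequence is
#' uniform over the residues; along each branch every site receives
#' `Poisson(rate * branch_time * site_factor)` substitution events, each
#' replacing the residue with one of the other 19 uniformly. Optional
#' gamma-distributed site factors (shape `alpha`, mean 1) add
#' across-site rate variation. Under this model the expected p-distance
#' between two tips diverged `t` Mya is
#' `(19/20) (1 - exp(-(20/19) * 2 * rate * t))`, giving a closed-form check
#' of the simulator.
#'
#' @param tree rooted `phylo` with branch lengths in million years.
#' @param rate substitution rate in substitutions/site/Mya (> 0).
#' @param sites number of alignment columns.
#' @param alpha optional gamma shape for site-rate variation.
#' @param seed integer seed.
#' @return List with `alignment` (named character vector of tip rows) and
#'   `truth`.
#' @export
evolve_alignment <- function(tree, rate, sites = 2000L, alpha = NULL,
                             seed = 1L) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo", call. = FALSE)
  if (rate <= 0) stop("`rate` must be > 0", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    factor <- if (is.null(alpha)) rep(1, sites) else {
      f <- rgamma(sites, shape = alpha, rate = alpha)
      f / mean(f)
    }
    n_tip <- length(tree$tip.label)
    root <- n_tip + 1L
    seqs <- vector("list", n_tip + tree$Nnode)
    seqs[[root]] <- sample.int(20L, sites, TRUE)
    tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
    for (k in seq_len(nrow(tr$edge))) {
      parent <- tr$edge[k, 1L]; child <- tr$edge[k, 2L]
      t_branch <- tr$edge.length[k]
      s <- seqs[[parent]]
      nsub <- rpois(sites, rate * t_branch * factor)
      for (j in seq_len(max(nsub, 0L))) {
        idx <- which(nsub >= j)
        if (!length(idx)) break
        u <- sample.int(19L, length(idx), TRUE)
        s[idx] <- u + (u >= s[idx])
      }
      seqs[[child]] <- s
    }
    rows <- vapply(seq_len(n_tip),
                   function(i) paste(AA20[seqs[[i]]], collapse = ""),
                   character(1))
    list(alignment = setNames(rows, tree$tip.label),
         truth = truth_record("evolve_alignment", seed,
                              list(rate = rate, sites = sites,
                                   alpha = alpha,
                                   tree = ape::write.tree(tree))))
  })
}

#' Synthetic membrane-ring time-lapse with contact enrichment
#'
#' Emulates a bead-contact recording: a circular membrane ring of uniform
#' base intensity, a contact arc whose intensity jumps to `fold * base`
#' from the onset frame onward, optional Gaussian blur (separable kernel,
#' an idealized point-spread function) and optional Poisson photon noise.
#' Ground-truth contact, reference and background masks are returned, so
#' the expected normalized fluorescence plateau is exactly `fold` in the
#' noiseless unblurred case.
#'
#' @param size image side in pixels (square frames).
#' @param radius,thickness ring centre-line radius and thickness (px).
#' @param arc contact arc as `c(start, end)` angles in radians.
#' @param fold contact enrichment factor (>= 1).
#' @param onset first frame (1-based) at which the contact is enriched.
#' @param n_frames number of frames.
#' @param base mean photon counts per ring pixel.
#' @param psf_sigma Gaussian blur sigma in px (0 = none).
#' @param noise `"none"` or `"poisson"`.
#' @param seed integer seed (used only for Poisson noise).
#' @return List with `stack` (size x size x n_frames array), `masks`
#'   (logical `contact`, `reference`, `background`), and `truth`.
#' @export
gen_cell_stack <- function(size = 64L, radius = 20, thickness = 5,
                           arc = c(-pi / 4, pi / 4), fold = 3,
                           onset = 5L, n_frames = 30L, base = 100,
                           psf_sigma = 0, noise = c("poisson", "none"),
                           seed = 1L) {
  noise <- match.arg(noise)
  if (thickness <= 0) stop("ring thickness must be > 0", call. = FALSE)
  if (fold < 1) stop("`fold` must be >= 1", call. = FALSE)
  ctr <- (size + 1) / 2
  xy <- expand.grid(row = seq_len(size), col = seq_len(size))
  dx <- xy$col - ctr; dy <- xy$row - ctr
  rr <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  ring <- matrix(abs(rr - radius) <= thickness / 2, size, size)
  in_arc <- matrix(theta >= arc[1L] & theta <= arc[2L], size, size)
  contact <- ring & in_arc
  reference <- ring & !in_arc
  background <- matrix(rr > radius + thickness, size, size)
  if (!any(contact)) stop("contact arc misses the ring", call. = FALSE)
  stack <- array(0, c(size, size, n_frames))
  for (t in seq_len(n_frames)) {
    fr <- matrix(0, size, size)
    fr[ring] <- base
    if (t >= onset) fr[contact] <- fold * base
    if (psf_sigma > 0) fr <- gaussian_blur(fr, psf_sigma)
    stack[, , t] <- fr
  }
  if (noise == "poisson")
    stack <- withr::with_seed(as.integer(seed), {
      array(as.double(rpois(length(stack), stack)), dim(stack))
    })
  list(stack = stack,
       masks = list(contact = contact, reference = reference,
                    background = background),
       truth = truth_record("gen_cell_stack", seed,
                            list(size = size, radius = radius,
                                 thickness = thickness, arc = arc,
                                 fold = fold, onset = onset,
                                 n_frames = n_frames, base = base,
                                 psf_sigma = psf_sigma, noise = noise)))
}

# Separable Gaussian convolution with reflected borders; kernel truncated
# at 3 sigma.
gaussian_blur <- function(img, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- k / sum(k)
  reflect <- function(i, n) {
    i[i < 1L] <- 2L - i[i < 1L]
    i[i > n] <- 2L * n - i[i > n]
    i
  }
  conv1 <- function(m) {        # along rows (first margin)
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (o in seq_along(k))
      out <- out + k[o] * m[reflect(seq_len(n) + o - half - 1L, n), ,
                            drop = FALSE]
    out
  }
  t(conv1(t(conv1(img))))
}

#' Synthetic vesicle image on a contact pattern
#'
#' A disc-shaped vesicle of uniform intensity with a central pattern-contact
#' region enriched `fold`-fold, optionally Poisson noised — ground truth for
#' [pattern_fold_change()].
#'
#' @param size image side (px).
#' @param vesicle_radius,pattern_radius disc radii (px).
#' @param fold enrichment of the pattern region.
#' @param base mean counts per vesicle pixel.
#' @param noise `"none"` or `"poisson"`.
#' @param seed integer seed.
#' @return List with `image`, `masks` (`pattern`, `vesicle`), `truth`.
#' @export
gen_vesicle_image <- function(size = 48L, vesicle_radius = 18,
                              pattern_radius = 8, fold = 3, base = 100,
                              noise = c("poisson", "none"), seed = 1L) {
  noise <- match.arg(noise)
  ctr <- (size + 1) / 2
  xy <- expand.grid(row = seq_len(size), col = seq_len(size))
  rr <- matrix(sqrt((xy$col - ctr)^2 + (xy$row - ctr)^2), size, size)
  vesicle <- rr <= vesicle_radius
  pattern <- rr <= pattern_radius
  img <- matrix(0, size, size)
  img[vesicle] <- base
  img[pattern] <- fold * base
  if (noise == "poisson")
    img <- withr::with_seed(as.integer(seed),
                            matrix(as.double(rpois(length(img), img)),
                                   size, size))
  list(image = img, masks = list(pattern = pattern, vesicle = vesicle),
       truth = truth_record("gen_vesicle_image", seed,
                            list(size = size,
                                 vesicle_radius = vesicle_radius,
                                 pattern_radius = pattern_radius,
                                 fold = fold, base = base,
                                 noise = noise)))
}

#' Synthetic Hertz force-indentation curves
#'
#' Samples the Hertz force law on an indentation grid (defaults mirror
#' stiff-bead nanoindentation: a few-nanometre indentation range and a
#' micron-scale probe) with optional multiplicative Gaussian noise and an
#' optional planted contact-point offset.
#'
#' @param E Young's modulus (Pa).
#' @param R probe radius (m).
#' @param nu Poisson ratio.
#' @param delta_max_nm maximum indentation (nm).
#' @param n_points samples per curve.
#' @param noise_sd multiplicative Gaussian noise s.d. (0.01 = 1%).
#' @param delta0_nm planted contact-point offset (nm).
#' @param n_curves number of curves.
#' @param seed integer seed.
#' @return List with `curves` (list of [force_curve()] objects) and
#'   `truth`.
#' @export
gen_force_curves <- function(E = 3e9, R = 1.5e-6, nu = 0.33,
                             delta_max_nm = 8, n_points = 60L,
                             noise_sd = 0, delta0_nm = 0, n_curves = 1L,
                             seed = 1L) {
  if (E <= 0 || R <= 0) stop("E and R must be positive", call. = FALSE)
  delta_nm <- seq(0, delta_max_nm, length.out = n_points)
  withr::with_seed(as.integer(seed), {
    curves <- lapply(seq_len(n_curves), function(i) {
      f <- hertz_force(pmax(delta_nm - delta0_nm, 0) * 1e-9, E, R, nu)
      if (noise_sd > 0) f <- f * (1 + rnorm(n_points, 0, noise_sd))
      suppressMessages(force_curve(delta_nm, f * 1e9, R * 1e9, nu))
    })
    list(curves = curves,
         truth = truth_record("gen_force_curves", seed,
                              list(E = E, R = R, nu = nu,
                                   delta_max_nm = delta_max_nm,
                                   n_points = n_points,
                                   noise_sd = noise_sd,
                                   delta0_nm = delta0_nm,
                                   n_curves = n_curves)))
  })
}

#' Synthetic stiffness-phagocytosis table
#'
#' Groups of strictly increasing stiffness (a crosslinking ladder from soft
#' to stiff polystyrene) and a monotone efficiency link plus optional
#' noise — the ground truth for the exact Spearman stiffness-uptake test.
#'
#' @param n_groups number of bead groups (>= 3; default 5).
#' @param stiffness_gpa strictly increasing stiffness values (GPa).
#' @param link monotone function mapping stiffness to efficiency.
#' @param noise_sd s.d. of additive Gaussian noise on the efficiency.
#' @param seed integer seed.
#' @return List with `table` (data frame `group`, `stiffness_gpa`,
#'   `efficiency`) and `truth`.
#' @export
gen_stiffness_phago <- function(n_groups = 5L,
                                stiffness_gpa = seq(0.5, 3,
                                                    length.out = n_groups),
                                link = function(s) 20 + 25 * log1p(s),
                                noise_sd = 0, seed = 1L) {
  if (n_groups < 3L) stop("need at least 3 groups", call. = FALSE)
  if (any(diff(stiffness_gpa) <= 0))
    stop("stiffness must be strictly increasing", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    eff <- link(stiffness_gpa) + rnorm(n_groups, 0, noise_sd)
    list(table = data.frame(group = paste0("XL", seq_len(n_groups)),
                            stiffness_gpa = stiffness_gpa,
                            efficiency = eff, stringsAsFactors = FALSE),
         truth = truth_record("gen_stiffness_phago", seed,
                              list(n_groups = n_groups,
                                   stiffness_gpa = stiffness_gpa,
                                   noise_sd = noise_sd)))
  })
}
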
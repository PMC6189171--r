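#' @importFrom stats as.dist cor pt rgamma rnorm rpois runif setNames
NULL

ALIGN_UNKNOWN <- c("-", ".", "X", "B", "Z", "*", "?")

# Named character vector of equal-length aligned rows -> character matrix
# (taxa x sites, uppercase).
alignment_matrix <- function(alignment) {
  if (inherits(alignment, "AAStringSet") || inherits(alignment, "XStringSet")) {
    v <- as.character(alignment)
    names(v) <- sub("\\s.*$", "", names(alignment))
    alignment <- v
  }
  if (is.matrix(alignment)) return(toupper(alignment))
  if (!is.character(alignment) || is.null(names(alignment)))
    stop("alignment must be a named character vector, matrix or AAStringSet",
         call. = FALSE)
  L <- unique(nchar(alignment))
  if (length(L) != 1L)
    stop("aligned rows must all have the same length", call. = FALSE)
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(m) <- names(alignment)
  m
}

#' Amino-acid distance between two aligned rows
#'
#' Computes the proportion of differing residues over usable columns
#' (pairwise deletion: any column where either row holds a gap or unknown
#' symbol is excluded) and, optionally, a multiple-hit correction:
#'
#' * `"p"` — the raw p-distance;
#' * `"poisson"` — `-ln(1 - p)`, the Poisson correction;
#' * `"gamma"` — `alpha * ((1 - p)^(-1/alpha) - 1)`, rate variation across
#'   sites with gamma shape `alpha`.
#'
#' Corrected distances diverge as p approaches 1; saturated pairs (`p = 1`)
#' are an error under the corrected models.
#'
#' @param a,b aligned residue strings (or character vectors of residues) of
#'   equal length.
#' @param model `"poisson"` (default), `"p"`, or `"gamma"`.
#' @param alpha gamma shape parameter (> 0), used only for `model = "gamma"`.
#' @return Distance in substitutions per site.
#' @examples
#' pairwise_distance("AAAAAAAAAA", "AAAAAAAAAC", model = "p")  # 0.1
#' @export
pairwise_distance <- function(a, b, model = c("poisson", "p", "gamma"),
                              alpha = 1) {
  model <- match.arg(model)
  ca <- if (length(a) == 1L) strsplit(toupper(a), "")[[1]] else toupper(a)
  cb <- if (length(b) == 1L) strsplit(toupper(b), "")[[1]] else toupper(b)
  if (length(ca) != length(cb))
    stop("aligned rows must have equal length", call. = FALSE)
  usable <- !(ca %in% ALIGN_UNKNOWN | cb %in% ALIGN_UNKNOWN)
  n <- sum(usable)
  if (n == 0L) stop("no usable columns between the two rows", call. = FALSE)
  p <- sum(ca[usable] != cb[usable]) / n
  correct_distance(p, model, alpha)
}

correct_distance <- function(p, model, alpha = 1) {
  switch(model,
    p = p,
    poisson = {
      if (any(p >= 1))
        stop("saturated distance (p = 1) under the poisson model",
             call. = FALSE)
      -log(1 - p)
    },
    gamma = {
      if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
        stop("gamma shape `alpha` must be > 0", call. = FALSE)
      if (any(p >= 1))
        stop("saturated distance (p = 1) under the gamma model",
             call. = FALSE)
      alpha * ((1 - p)^(-1 / alpha) - 1)
    })
}

#' All pairwise amino-acid distances of an alignment
#'
#' @param alignment named character vector of equal-length aligned rows, a
#'   character matrix (taxa x sites) or an `AAStringSet`.
#' @inheritParams pairwise_distance
#' @return A symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
aa_distance_matrix <- function(alignment, model = c("poisson", "p", "gamma"),
                               alpha = 1) {
  model <- match.arg(model)
  m <- alignment_matrix(alignment)
  n <- nrow(m)
  usable <- !matrix(m %in% ALIGN_UNKNOWN, n, ncol(m))
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    u <- usable[i, ] & usable[j, ]
    nu <- sum(u)
    if (nu == 0L)
      stop("no usable columns between ", rownames(m)[i], " and ",
           rownames(m)[j], call. = FALSE)
    p <- sum(m[i, u] != m[j, u]) / nu
    D[i, j] <- D[j, i] <- correct_distance(p, model, alpha)
  }
  D
}
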
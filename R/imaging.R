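#' Sampling line for profiles and kymographs
#'
#' Pixel coordinates are 0-based, `x` to the right (columns), `y` down
#' (rows). `width` is the size in pixels of the averaging band perpendicular
#' to the line.
#'
#' @param x0,y0,x1,y1 endpoint coordinates (0-based, in pixels).
#' @param width averaging band width in pixels (odd values center the band
#'   on the line).
#' @return An object of class `profile_line`.
#' @export
profile_line <- function(x0, y0, x1, y1, width = 1L) {
  if (x0 == x1 && y0 == y1) stop("line endpoints must differ", call. = FALSE)
  if (width < 1L) stop("width must be >= 1", call. = FALSE)
  structure(list(p0 = c(x = x0, y = y0), p1 = c(x = x1, y = y1),
                 width = as.integer(width)),
            class = "profile_line")
}

# Bilinear interpolation of frame (matrix, row = y) at 0-based (x, y).
bilinear <- function(frame, x, y) {
  H <- nrow(frame); W <- ncol(frame)
  if (any(x < 0 | x > W - 1 | y < 0 | y > H - 1))
    stop("sampling position outside the frame", call. = FALSE)
  x0 <- pmin(floor(x), W - 2); y0 <- pmin(floor(y), H - 2)
  fx <- x - x0; fy <- y - y0
  i <- y0 + 1L; j <- x0 + 1L
  frame[cbind(i, j)]         * (1 - fx) * (1 - fy) +
    frame[cbind(i, j + 1L)]     * fx     * (1 - fy) +
    frame[cbind(i + 1L, j)]     * (1 - fx) * fy +
    frame[cbind(i + 1L, j + 1L)] * fx     * fy
}

#' Intensity profile along a line
#'
#' Samples the frame at unit-pixel spacing along the line with bilinear
#' interpolation, averaging across the `width`-pixel band perpendicular to
#' the line — the standard way fluorescence intensity is read out across a
#' phagocytic cup.
#'
#' @param frame numeric matrix of intensities (rows = y).
#' @param line a [profile_line()].
#' @return Numeric vector of samples, from `p0` to `p1`.
#' @export
line_profile <- function(frame, line) {
  if (!inherits(line, "profile_line"))
    stop("`line` must be a profile_line", call. = FALSE)
  if (!is.matrix(frame) || !is.numeric(frame))
    stop("`frame` must be a numeric matrix", call. = FALSE)
  d <- line$p1 - line$p0
  len <- sqrt(sum(d^2))
  u <- d / len
  nrm <- c(-u[2L], u[1L])                 # unit normal
  steps <- seq(0, floor(len))
  offs <- seq_len(line$width) - (line$width + 1) / 2
  acc <- matrix(0, length(steps), length(offs))
  for (k in seq_along(offs)) {
    x <- line$p0[["x"]] + steps * u[1L] + offs[k] * nrm[1L]
    y <- line$p0[["y"]] + steps * u[2L] + offs[k] * nrm[2L]
    acc[, k] <- bilinear(frame, x, y)
  }
  rowMeans(acc)
}

check_stack <- function(stack) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  if (!is.array(stack) || length(dim(stack)) != 3L || dim(stack)[3L] < 1L)
    stop("`stack` must be an H x W x T array with at least one frame",
         call. = FALSE)
  if (!all(is.finite(stack)))
    stop("stack intensities must be finite", call. = FALSE)
  stack
}

#' Kymograph of a time-lapse stack along a line
#'
#' Row `t` is `line_profile(frame_t, line)`: position along the line runs
#' across columns, time down rows, so a structure moving along the line
#' appears as a tilted ridge.
#'
#' @param stack numeric H x W x T array.
#' @param line a [profile_line()].
#' @return T x L numeric matrix.
#' @export
kymograph <- function(stack, line) {
  stack <- check_stack(stack)
  t(apply(stack, 3L, line_profile, line = line))
}

check_mask <- function(mask, frame_dim, what) {
  if (!is.matrix(mask) || !is.logical(mask) ||
      !all(dim(mask) == frame_dim))
    stop(what, " mask must be a logical matrix matching the frame shape",
         call. = FALSE)
  if (!any(mask)) stop(what, " mask is empty", call. = FALSE)
  mask
}

#' Normalized fluorescence at a contact site
#'
#' Per frame, the ratio of the mean intensity within the contact mask to the
#' mean within the reference (non-contact membrane) mask; when a background
#' mask is supplied its per-frame mean is subtracted from both. This is the
#' enrichment readout used for lipid and ERM recruitment at a bead contact.
#' Frames whose denominator falls below a floor (`1e-6` times the global
#' mean intensity) yield `NA` rather than an unstable spike.
#'
#' @param stack numeric H x W x T array.
#' @param contact,reference logical masks (disjoint, nonempty).
#' @param background optional logical mask for background subtraction.
#' @return Numeric vector of length T.
#' @export
normalized_fluorescence <- function(stack, contact, reference,
                                    background = NULL) {
  stack <- check_stack(stack)
  d <- dim(stack)[1:2]
  contact <- check_mask(contact, d, "contact")
  reference <- check_mask(reference, d, "reference")
  if (any(contact & reference))
    stop("contact and reference masks overlap", call. = FALSE)
  if (!is.null(background)) background <- check_mask(background, d,
                                                     "background")
  floor_val <- 1e-6 * mean(stack)
  vapply(seq_len(dim(stack)[3L]), function(t) {
    fr <- stack[, , t]
    bg <- if (is.null(background)) 0 else mean(fr[background])
    num <- mean(fr[contact]) - bg
    den <- mean(fr[reference]) - bg
    if (den < floor_val) NA_real_ else num / den
  }, numeric(1))
}

#' Fold change of intensity on a contact pattern
#'
#' Ratio of the mean intensity over the pattern-contacting pixels to the
#' mean over the non-contacting pixels of the same vesicle, optionally after
#' background subtraction — the per-vesicle enrichment statistic for lipid
#' sorting onto fabricated micropatterns (PIP2 shows roughly 3-fold
#' enrichment in this assay).
#'
#' @param image numeric matrix.
#' @param pattern logical mask of pattern-contacting pixels.
#' @param vesicle logical mask of the vesicle footprint (default: the whole
#'   image); the complement of `pattern` within it must be nonempty.
#' @param background optional logical mask whose mean is subtracted from
#'   both means.
#' @return Scalar fold change.
#' @export
pattern_fold_change <- function(image, pattern, vesicle = NULL,
                                background = NULL) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("`image` must be a numeric matrix", call. = FALSE)
  d <- dim(image)
  pattern <- check_mask(pattern, d, "pattern")
  if (is.null(vesicle)) vesicle <- matrix(TRUE, d[1L], d[2L])
  vesicle <- check_mask(vesicle, d, "vesicle")
  rest <- vesicle & !pattern
  if (!any(rest))
    stop("the complement of the pattern within the vesicle is empty",
         call. = FALSE)
  bg <- if (is.null(background)) 0 else
    mean(image[check_mask(background, d, "background")])
  (mean(image[pattern & vesicle]) - bg) / (mean(image[rest]) - bg)
}

#' Generalized polarization map
#'
#' Per-pixel ratiometric index `GP = (I_o - I_d) / (I_o + I_d)` contrasting
#' an ordered-phase channel against a disordered-phase channel (c-Laurdan
#' style lipid-packing readout). Pixels whose total intensity falls below
#' the floor are `NA`. GP lies in \[-1, 1\] wherever defined.
#'
#' @param ordered,disordered nonnegative numeric matrices of equal shape.
#' @param floor minimum `I_o + I_d` for a defined pixel; default `1e-6`
#'   times the mean total intensity.
#' @return Numeric matrix of GP values.
#' @export
gp_ratio <- function(ordered, disordered, floor = NULL) {
  if (!is.matrix(ordered) || !is.matrix(disordered) ||
      !all(dim(ordered) == dim(disordered)))
    stop("channels must be matrices of the same shape", call. = FALSE)
  if (any(ordered < 0) || any(disordered < 0))
    stop("channel intensities must be nonnegative", call. = FALSE)
  tot <- ordered + disordered
  if (is.null(floor)) floor <- 1e-6 * mean(tot)
  gp <- (ordered - disordered) / tot
  gp[tot < floor] <- NA_real_
  gp
}
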
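#' Read and write FASTA protein sets
#'
#' Thin wrappers over Biostrings that present sequences as a named
#' character vector; writing then reading is the identity on record IDs and
#' residues regardless of line wrapping.
#'
#' @param path file path.
#' @param sequences named character vector of residue strings.
#' @param width line-wrap width for writing.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such FASTA file: ", path, call. = FALSE)
  ss <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e)
                   stop("unreadable FASTA ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path, width = 80L) {
  ss <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read and write Newick trees with supports as internal-node labels
#'
#' @param path file path.
#' @param tree a `phylo` object; bootstrap supports, if present, travel in
#'   `node.label`.
#' @return `read_newick()` returns a `phylo`.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e)
                   stop("unreadable Newick ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("unreadable Newick ", path, call. = FALSE)
  tr
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read and write tab-separated tables
#'
#' @param path file path.
#' @param table a data frame.
#' @return `read_tsv_table()` returns a data frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write multi-page TIFF stacks
#'
#' Stacks are H x W x T arrays of photon counts stored as 16-bit unsigned
#' multi-page TIFF, the standard microscopy interchange format. Any
#' integer-valued stack in `[0, 65535]` round-trips voxel-identically;
#' non-integer intensities are rejected rather than silently quantized.
#'
#' @param path file path.
#' @param stack numeric H x W x T array (a matrix is treated as one frame)
#'   of integer counts in `[0, 65535]`.
#' @return `read_stack_tiff()` returns an H x W x T array of counts.
#' @export
read_stack_tiff <- function(path) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop("unreadable TIFF ", path, ": ",
                           conditionMessage(e), call. = FALSE))
  if (is.matrix(pages)) pages <- list(pages)
  round(array(unlist(pages), c(dim(pages[[1L]]), length(pages))) * 65535)
}

#' @rdname read_stack_tiff
#' @export
write_stack_tiff <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  storage.mode(stack) <- "double"
  if (any(stack < 0) || max(stack) > 65535 ||
      max(abs(stack - round(stack))) > 1e-9)
    stop("16-bit TIFF stacks store integer photon counts in [0, 65535]",
         call. = FALSE)
  pages <- lapply(seq_len(dim(stack)[3L]),
                  function(t) round(stack[, , t]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}
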
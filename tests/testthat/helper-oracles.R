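# Independent oracles, kept deliberately naive so they share no code path
# with the implementation.

# Exhaustive (start, spacer) enumeration over character vectors.
brute_force_scan <- function(sequence, spacer_min = 6L, spacer_max = 12L) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  hits <- list()
  for (s in spacer_min:spacer_max) {
    for (i in seq_len(max(0L, n - (7L + s)))) {
      if (ch[i] == "Y" && ch[i + 3L] %in% c("L", "I") &&
          ch[i + 4L + s] == "Y" && ch[i + 7L + s] %in% c("L", "I"))
        hits[[length(hits) + 1L]] <- c(start = i, spacer = s)
    }
  }
  if (!length(hits))
    return(data.frame(start = integer(), spacer = integer()))
  out <- as.data.frame(do.call(rbind, hits))
  out[order(out$start, out$spacer), , drop = FALSE]
}

# Vectorized variant used for bulk cross-checks (still independent of the
# regex scanner: plain positional comparisons).
vector_scan <- function(sequence, spacer_min = 6L, spacer_max = 12L) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  out <- list()
  for (s in spacer_min:spacer_max) {
    m <- n - (7L + s)
    if (m < 1L) next
    i <- seq_len(m)
    hit <- ch[i] == "Y" & ch[i + 3L] %in% c("L", "I") &
      ch[i + 4L + s] == "Y" & ch[i + 7L + s] %in% c("L", "I")
    if (any(hit))
      out[[length(out) + 1L]] <- data.frame(start = i[hit], spacer = s)
  }
  if (!length(out)) return(data.frame(start = integer(), spacer = integer()))
  res <- do.call(rbind, out)
  res[order(res$start, res$spacer), , drop = FALSE]
}

random_seq <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, TRUE),
        collapse = "")
}

# Random ultrametric-free tree with positive branch lengths, for additive
# NJ recovery checks.
random_branch_tree <- function(n_tips) {
  tr <- ape::rtree(n_tips, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.05, 1)
  tr
}
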
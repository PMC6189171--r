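#' Degenerate two-half-site ITAM probe
#'
#' Describes the loose immunoreceptor tyrosine-based activation motif used to
#' scan proteomes: two Y-x-x-(L/I) half-sites separated by a variable spacer.
#' The default is the probe Y-x-x-(L/I)-x(6-12)-Y-x-x-(L/I); residue numbering
#' of Moesin places such a pair at Y191/Y205, a 10-residue spacer.
#'
#' @param anchor1,anchor2 single residue accepted at the half-site anchor
#'   position (default tyrosine).
#' @param tail1,tail2 residue set accepted three positions after the anchor
#'   (default leucine or isoleucine).
#' @param spacer_min,spacer_max inclusive bounds, in residues, on the spacer
#'   between the first half-site's tail and the second half-site's anchor.
#' @return An object of class `motif_pattern`.
#' @examples
#' motif_pattern()
#' @export
motif_pattern <- function(anchor1 = "Y", tail1 = c("L", "I"),
                          spacer_min = 6L, spacer_max = 12L,
                          anchor2 = "Y", tail2 = c("L", "I")) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  chk <- function(x, what) {
    x <- toupper(as.character(x))
    if (length(x) < 1L || !all(nchar(x) == 1L) || !all(x %in% aa))
      stop("pattern ", what, " must be drawn from the 20-letter amino-acid ",
           "alphabet", call. = FALSE)
    x
  }
  anchor1 <- chk(anchor1, "anchor1"); anchor2 <- chk(anchor2, "anchor2")
  if (length(anchor1) != 1L || length(anchor2) != 1L)
    stop("anchors must be single residues", call. = FALSE)
  tail1 <- chk(tail1, "tail1"); tail2 <- chk(tail2, "tail2")
  spacer_min <- as.integer(spacer_min); spacer_max <- as.integer(spacer_max)
  if (is.na(spacer_min) || is.na(spacer_max) || spacer_min <= 0L ||
      spacer_min > spacer_max)
    stop("need 0 < spacer_min <= spacer_max", call. = FALSE)
  structure(list(anchor1 = anchor1, tail1 = tail1,
                 spacer_min = spacer_min, spacer_max = spacer_max,
                 anchor2 = anchor2, tail2 = tail2),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern> %s-x-x-(%s)-x(%d-%d)-%s-x-x-(%s)\n",
              x$anchor1, paste(x$tail1, collapse = "/"),
              x$spacer_min, x$spacer_max,
              x$anchor2, paste(x$tail2, collapse = "/")))
  invisible(x)
}

half_site_regex <- function(anchor, tail) {
  sprintf("%s..[%s]", anchor, paste(tail, collapse = ""))
}

#' Scan one protein sequence for the degenerate ITAM probe
#'
#' Reports every `(start, spacer)` combination matching the two-half-site
#' pattern, including overlapping and nested matches. Coordinates are 1-based
#' and inclusive, so a Moesin-like hit has `start = 191`, `spacer = 10`,
#' `end = 208`. Unknown symbols (`X`, `B`, `Z`, `*`) never satisfy an anchor
#' or tail position but may occupy the unconstrained positions.
#'
#' @param sequence character scalar of uppercase one-letter residue codes.
#' @param pattern a [motif_pattern()].
#' @return A data frame with columns `start`, `spacer`, `end`, `matched_seq`,
#'   sorted by `(start, spacer)`; zero rows when there is no match.
#' @examples
#' scan_sequence("YAALGGGGGGYAAI")
#' @export
scan_sequence <- function(sequence, pattern = motif_pattern()) {
  if (!inherits(pattern, "motif_pattern"))
    stop("`pattern` must be a motif_pattern", call. = FALSE)
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("`sequence` must be a single character string", call. = FALSE)
  sequence <- toupper(sequence)
  h1 <- half_site_regex(pattern$anchor1, pattern$tail1)
  h2 <- half_site_regex(pattern$anchor2, pattern$tail2)
  out <- vector("list", pattern$spacer_max - pattern$spacer_min + 1L)
  for (s in pattern$spacer_min:pattern$spacer_max) {
    # lookahead so overlapping matches are all reported
    re <- sprintf("(?=%s.{%d}%s)", h1, s, h2)
    m <- gregexpr(re, sequence, perl = TRUE)[[1]]
    if (m[1L] == -1L) next
    starts <- as.integer(m)
    out[[s - pattern$spacer_min + 1L]] <- data.frame(
      start = starts, spacer = s, end = starts + 7L + s,
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, out)
  if (is.null(hits))
    return(data.frame(start = integer(), spacer = integer(),
                      end = integer(), matched_seq = character(),
                      stringsAsFactors = FALSE))
  hits <- hits[order(hits$start, hits$spacer), , drop = FALSE]
  hits$matched_seq <- substring(sequence, hits$start, hits$end)
  rownames(hits) <- NULL
  hits
}

#' Scan a proteome for ITAM-probe hits
#'
#' One row per protein carrying at least one match; a protein with several
#' matches counts once ("independent hit" means a unique protein), with the
#' number of matches stored in `hit_count`.
#'
#' @param proteome a named character vector of sequences, a
#'   [Biostrings::AAStringSet], or the path of a FASTA file.
#' @param pattern a [motif_pattern()].
#' @param gene_map optional named character vector mapping protein IDs to gene
#'   symbols; unmapped proteins use their own ID.
#' @return A candidate table: data frame with `protein_id`, `gene`,
#'   `hit_count`, `first_start`, `first_spacer`.
#' @export
scan_proteome <- function(proteome, pattern = motif_pattern(),
                          gene_map = NULL) {
  seqs <- as_protein_set(proteome)
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every proteome record needs an ID", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate protein IDs in proteome: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  rows <- lapply(ids, function(id) {
    h <- scan_sequence(seqs[[id]], pattern)
    if (nrow(h) == 0L) return(NULL)
    data.frame(protein_id = id, hit_count = nrow(h),
               first_start = h$start[1L], first_spacer = h$spacer[1L],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(protein_id = character(), hit_count = integer(),
                      first_start = integer(), first_spacer = integer(),
                      stringsAsFactors = FALSE)
  gene <- tab$protein_id
  if (!is.null(gene_map)) {
    hit <- tab$protein_id %in% names(gene_map)
    gene[hit] <- unname(gene_map[tab$protein_id[hit]])
  }
  tab <- cbind(tab[, "protein_id", drop = FALSE], gene = gene,
               tab[, c("hit_count", "first_start", "first_spacer")])
  rownames(tab) <- NULL
  tab
}

# Accepts named character vector, AAStringSet or FASTA path; returns a plain
# named character list of uppercase sequences.
as_protein_set <- function(x) {
  if (inherits(x, "AAStringSet") || inherits(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(as.list(toupper(out)))
  }
  if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
      file.exists(x)) {
    ss <- Biostrings::readAAStringSet(x)
    return(as_protein_set(ss))
  }
  if (is.character(x)) return(as.list(toupper(x)))
  if (is.list(x)) return(lapply(x, function(s) toupper(as.character(s))))
  stop("cannot interpret `proteome`", call. = FALSE)
}

#' Rank motif-bearing candidates by expression abundance
#'
#' Mirrors the screen's expression step: motif-bearing proteins are ranked
#' within each abundance dataset by percentile rank (rank / n, midranks for
#' ties; a gene absent from a dataset scores 0), and datasets are aggregated
#' by the mean percentile rank. Rows are sorted by decreasing aggregate score
#' with ties broken lexicographically by gene symbol, and the top `n_top`
#' rows are flagged.
#'
#' Percentile ranks are scale-free, so abundance units (counts, FPKM, TPM)
#' may differ between datasets.
#'
#' @param table candidate table from [scan_proteome()] (needs a `gene`
#'   column).
#' @param expression list (ideally named) of data frames with columns `gene`
#'   and `abundance`.
#' @param n_top number of rows to flag as top candidates (default 25, the
#'   screen's shortlisting depth).
#' @return The table with per-dataset `rank_*` columns, `score` (mean
#'   percentile rank, in \[0, 1\]) and logical `top`.
#' @export
rank_candidates <- function(table, expression, n_top = 25L) {
  if (!is.data.frame(table) || !"gene" %in% names(table))
    stop("`table` must be a candidate table with a `gene` column",
         call. = FALSE)
  if (!is.list(expression) || length(expression) == 0L ||
      is.data.frame(expression))
    stop("`expression` must be a non-empty list of abundance tables",
         call. = FALSE)
  nm <- names(expression)
  if (is.null(nm) || any(!nzchar(nm)))
    nm <- paste0("dataset", seq_along(expression))
  ranks <- matrix(0, nrow(table), length(expression),
                  dimnames = list(NULL, paste0("rank_", nm)))
  for (k in seq_along(expression)) {
    ds <- expression[[k]]
    if (!is.data.frame(ds) || !all(c("gene", "abundance") %in% names(ds)))
      stop("abundance table ", nm[k], " needs `gene` and `abundance` columns",
           call. = FALSE)
    if (any(ds$abundance < 0, na.rm = TRUE))
      stop("abundances must be nonnegative (", nm[k], ")", call. = FALSE)
    pr <- rank(ds$abundance, ties.method = "average") / nrow(ds)
    idx <- match(table$gene, ds$gene)
    ranks[, k] <- ifelse(is.na(idx), 0, pr[idx])
  }
  out <- cbind(table, as.data.frame(ranks))
  out$score <- rowMeans(ranks)
  ord <- order(-out$score, out$gene)
  out <- out[ord, , drop = FALSE]
  out$top <- seq_len(nrow(out)) <= n_top
  rownames(out) <- NULL
  out
}

#' Apply rule-based exclusion filters to a ranked candidate table
#'
#' Each candidate either passes all rules or is excluded with exactly one
#' primary reason: the highest-precedence rule it fails. Rules are data, not
#' code — a boolean annotation table whose columns are named rules (e.g.
#' `secreted`, `nuclear_only`, `itam_inaccessible`, `known_itam_receptor`),
#' mirroring the side notes of the screen's shortlisting step.
#'
#' @param table ranked candidate table (a `gene` column is required).
#' @param annotations data frame with a `gene` column and one logical column
#'   per exclusion rule; `TRUE` means the rule disqualifies the gene. Genes
#'   absent from the annotation table fail no rule.
#' @param rules character vector of rule names in decreasing precedence;
#'   default is the annotation column order. Unknown names are an error.
#' @return The table with logical `excluded` and character `reason` (`NA`
#'   for passing rows).
#' @seealso [shortlist()]
#' @export
apply_exclusions <- function(table, annotations, rules = NULL) {
  if (!is.data.frame(table) || !"gene" %in% names(table))
    stop("`table` must be a candidate table with a `gene` column",
         call. = FALSE)
  if (!is.data.frame(annotations) || !"gene" %in% names(annotations))
    stop("`annotations` must have a `gene` column", call. = FALSE)
  avail <- setdiff(names(annotations), "gene")
  if (is.null(rules)) rules <- avail
  unknown <- setdiff(rules, avail)
  if (length(unknown))
    stop("unknown exclusion rule(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  idx <- match(table$gene, annotations$gene)
  reason <- rep(NA_character_, nrow(table))
  for (r in rev(rules)) {            # later overwrite = higher precedence
    flag <- annotations[[r]][idx]
    flag[is.na(flag)] <- FALSE
    reason[flag] <- r
  }
  table$excluded <- !is.na(reason)
  table$reason <- reason
  table
}

#' Passing candidates in rank order
#'
#' @param table output of [apply_exclusions()].
#' @return The non-excluded rows, in their existing (rank) order.
#' @export
shortlist <- function(table) {
  if (!is.data.frame(table) || !"excluded" %in% names(table))
    stop("`table` must come from apply_exclusions()", call. = FALSE)
  out <- table[!table$excluded, , drop = FALSE]
  rownames(out) <- NULL
  out
}
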
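#' Physicochemical property partitions for CTD descriptors
#'
#' Loads a table of three-group partitions of the 20 standard amino acids,
#' one per physicochemical property. The shipped default is the classical
#' eight-property set used by the 188D protein descriptor (hydrophobicity,
#' normalized van der Waals volume, polarity, polarizability, charge,
#' secondary-structure propensity, solvent accessibility, surface tension).
#' Users may point `path` at their own table: tab-separated with columns
#' `property`, `group1`, `group2`, `group3`, residues comma-separated.
#' Each partition is validated: three pairwise-disjoint non-empty groups
#' whose union is exactly the 20 standard residues.
#'
#' @param path Path to a partition table; default the shipped table.
#'
#' @return Named list (one element per property) of lists of three character
#'   vectors of residues.
#' @export
ctd_properties <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ctd_properties.tsv", package = "pvpkit",
                        mustWork = TRUE)
  }
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  need <- c("property", "group1", "group2", "group3")
  if (!all(need %in% names(tab))) {
    stop("property table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  aa <- alphabet("protein")$symbols
  parts <- lapply(seq_len(nrow(tab)), function(r) {
    groups <- lapply(tab[r, c("group1", "group2", "group3")],
                     function(g) strsplit(g, ",", fixed = TRUE)[[1]])
    all_res <- unlist(groups)
    if (any(lengths(groups) == 0L) ||
        anyDuplicated(all_res) ||
        !setequal(all_res, aa)) {
      stop(sprintf(
        "property '%s': groups must be non-empty, disjoint, and cover the 20 standard residues",
        tab$property[r]), call. = FALSE)
    }
    unname(groups)
  })
  names(parts) <- tab$property
  parts
}

check_protein_seq <- function(seq, min_len = 1L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  L <- nchar(seq)
  if (L < min_len) {
    stop(sprintf("sequence '%s' must have length >= %d", names(seq) %||% "<sequence>",
                 min_len), call. = FALSE)
  }
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), alphabet("protein")$symbols)
  if (length(bad)) {
    stop(sprintf("sequence '%s' has non-standard residues: %s",
                 names(seq) %||% "<sequence>", paste(bad, collapse = ",")),
         call. = FALSE)
  }
  invisible(L)
}

group_index <- function(seq, partition) {
  ch <- strsplit(seq, "")[[1]]
  g <- integer(length(ch))
  for (j in 1:3) g[ch %in% partition[[j]]] <- j
  g
}

#' Amino-acid composition (AAC)
#'
#' Frequency of each of the 20 standard residues: `N_i / L`, where `N_i` is
#' the count of residue i and `L` the sequence length. Sums to 1.
#'
#' @param seq A valid protein residue string, length >= 1.
#' @return Named numeric vector of 20 frequencies in protein-alphabet order.
#' @export
aac <- function(seq) {
  L <- check_protein_seq(seq, 1L)
  syms <- alphabet("protein")$symbols
  counts <- tabulate(match(strsplit(seq, "")[[1]], syms), nbins = 20L)
  stats::setNames(counts / L, syms)
}

#' CTD composition (C) for one property
#'
#' Fraction of residues falling in each of the partition's three groups;
#' the three values sum to 1.
#'
#' @param seq A valid protein residue string, length >= 1.
#' @param partition List of three residue-character vectors (one element of
#'   [ctd_properties()]).
#' @return Numeric vector of 3 group frequencies.
#' @export
ctd_composition <- function(seq, partition) {
  L <- check_protein_seq(seq, 1L)
  g <- group_index(seq, partition)
  tabulate(g, nbins = 3L) / L
}

#' CTD transition (T) for one property
#'
#' Rate of adjacent residue pairs that cross between two different groups,
#' in either order, for the pairs (1,2), (1,3), (2,3); each divided by the
#' number of adjacent pairs, L - 1. A sequence confined to one group scores
#' (0, 0, 0); strict alternation between two groups scores 1 on that pair.
#'
#' @inheritParams ctd_composition
#' @return Numeric vector of 3 transition rates.
#' @export
ctd_transition <- function(seq, partition) {
  L <- check_protein_seq(seq, 2L)
  g <- group_index(seq, partition)
  a <- pmin(g[-L], g[-1L])
  b <- pmax(g[-L], g[-1L])
  c(sum(a == 1L & b == 2L), sum(a == 1L & b == 3L), sum(a == 2L & b == 3L)) / (L - 1L)
}

#' CTD distribution (D) for one property
#'
#' For each group, the relative chain positions (1-based position / L) at
#' which the group's first, 25%, 50%, 75% and last occurrences sit. With n
#' occurrences, the q-quantile anchor is occurrence `max(1, ceiling(q * n))`.
#' A group absent from the sequence contributes five zeros.
#'
#' @inheritParams ctd_composition
#' @return Numeric vector of 15 values (5 anchors x 3 groups, group-major).
#' @export
ctd_distribution <- function(seq, partition) {
  L <- check_protein_seq(seq, 1L)
  g <- group_index(seq, partition)
  out <- numeric(15L)
  for (j in 1:3) {
    pos <- which(g == j)
    n <- length(pos)
    if (n > 0L) {
      idx <- c(1L, pmax(1L, ceiling(c(0.25, 0.50, 0.75, 1.00) * n)))
      out[(j - 1L) * 5L + 1:5] <- pos[idx] / L
    }
  }
  out
}

#' The 188-dimensional protein descriptor
#'
#' Computes the classical 188D representation: 20 amino-acid composition
#' frequencies, followed, for each of the 8 physicochemical properties in
#' table order, by 3 composition (C), 3 transition (T) and 15 distribution
#' (D) values — (3 + 3 + 15) x 8 = 168 CTD features, 188 in total.
#'
#' @param seq A valid protein residue string, length >= 2 (transitions need
#'   at least one adjacent pair).
#' @param properties Property partitions, default [ctd_properties()].
#' @return Named numeric vector of length 188.
#' @export
encode_188d <- function(seq, properties = ctd_properties()) {
  check_protein_seq(seq, 2L)
  blocks <- lapply(names(properties), function(p) {
    part <- properties[[p]]
    stats::setNames(
      c(ctd_composition(seq, part), ctd_transition(seq, part),
        ctd_distribution(seq, part)),
      paste0(p, c("_C1", "_C2", "_C3", "_T12", "_T13", "_T23",
                  paste0("_D", rep(1:3, each = 5), "_",
                         rep(c("first", "p25", "p50", "p75", "p100"), 3))))
    )
  })
  a <- aac(seq)
  names(a) <- paste0("aac_", names(a))
  c(a, unlist(blocks))
}

#' Encode a batch of protein sequences as 188D rows
#'
#' @param seqs Named character vector of valid protein residue strings.
#' @param properties Property partitions, default [ctd_properties()].
#' @return Numeric matrix with one 188-column row per sequence.
#' @export
encode_188d_batch <- function(seqs, properties = ctd_properties()) {
  stopifnot(is.character(seqs))
  space_names <- names(encode_188d("AC", properties))
  m <- matrix(0, nrow = length(seqs), ncol = length(space_names),
              dimnames = list(names(seqs), space_names))
  for (r in seq_along(seqs)) m[r, ] <- encode_188d(seqs[r], properties)
  m
}
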
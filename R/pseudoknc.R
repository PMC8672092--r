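#' k-tuple composition feature space
#'
#' Enumerates the feature names of the k-tuple composition (kNC) encoder: all
#' i-mers over the alphabet for i = 1..k, grouped by ascending i and ordered
#' lexicographically within each block by the alphabet's declared symbol
#' order. The dimension obeys sum over i of |A|^i: 20, 420 and 8,420 for
#' protein at k = 1, 2, 3; 4, 20 and 84 for DNA/RNA.
#'
#' @param alphabet A [alphabet()] object or kind string.
#' @param k Maximum tuple length (the ktuple), integer in 1..5.
#'
#' @return Object of class `knc_space`: list with `alphabet`, `k`, `names`
#'   (ordered i-mer strings) and `block` (integer vector giving each name's
#'   i-mer length).
#' @export
kmer_feature_names <- function(alphabet, k) {
  alphabet <- as_alphabet(alphabet)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1) {
    stop("`k` must be an integer >= 1", call. = FALSE)
  }
  k <- as.integer(k)
  if (k > 5L) stop("`k` above 5 is not supported", call. = FALSE)
  syms <- alphabet$symbols
  blocks <- lapply(seq_len(k), function(i) {
    # expand.grid varies the first factor fastest; reverse so the leading
    # position is slowest and names sort by declared symbol order
    g <- do.call(expand.grid,
                 c(rep(list(syms), i), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE))
    do.call(paste0, rev(g))
  })
  structure(
    list(alphabet = alphabet, k = k,
         names = unlist(blocks, use.names = FALSE),
         block = rep(seq_len(k), lengths(blocks))),
    class = "knc_space"
  )
}

#' @export
print.knc_space <- function(x, ...) {
  cat(sprintf("<knc_space> %s, k = %d, %d features\n",
              x$alphabet$kind, x$k, length(x$names)))
  invisible(x)
}

#' Encode one sequence as a k-tuple composition vector
#'
#' Counts every i-mer of the space (i = 1..k) as a contiguous, overlapping
#' substring of the sequence. By default counts are normalised per block by
#' the number of windows (L - i + 1), so each i-mer block sums to 1 and the
#' features are length-invariant; raw counts are available with
#' `normalize = FALSE`.
#'
#' @param seq A single residue string, valid over the space's alphabet.
#' @param space A [kmer_feature_names()] space.
#' @param normalize Divide each block's counts by its window count
#'   (default `TRUE`).
#'
#' @return Named numeric vector aligned to `space$names`.
#' @export
encode_pseudoknc <- function(seq, space, normalize = TRUE) {
  stopifnot(inherits(space, "knc_space"), is.character(seq), length(seq) == 1L)
  L <- nchar(seq)
  id <- names(seq) %||% "<sequence>"
  if (L < space$k) {
    stop(sprintf("sequence '%s' is shorter (L = %d) than k = %d", id, L, space$k),
         call. = FALSE)
  }
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), space$alphabet$symbols)
  if (length(bad)) {
    stop(sprintf("sequence '%s' has characters outside the %s alphabet: %s",
                 id, space$alphabet$kind, paste(bad, collapse = ",")),
         call. = FALSE)
  }
  out <- numeric(length(space$names))
  names(out) <- space$names
  for (i in seq_len(space$k)) {
    starts <- seq_len(L - i + 1L)
    words <- substring(seq, starts, starts + i - 1L)
    sel <- space$block == i
    counts <- tabulate(match(words, space$names[sel]), nbins = sum(sel))
    out[sel] <- if (normalize) counts / length(starts) else counts
  }
  out
}

#' Encode a batch of sequences
#'
#' @param seqs Named character vector of residue strings.
#' @param space A [kmer_feature_names()] space, or an alphabet if `k` is
#'   given.
#' @param k Convenience: build the space from `space` (as alphabet) and `k`.
#' @param normalize Passed to [encode_pseudoknc()].
#'
#' @return Numeric matrix, one row per sequence (rownames = ids, original
#'   order), one column per feature name. Zero sequences give a 0-row matrix
#'   with the full column set.
#' @export
encode_knc <- function(seqs, space, k = NULL, normalize = TRUE) {
  if (!inherits(space, "knc_space")) {
    if (is.null(k)) stop("supply a knc_space or an alphabet plus `k`", call. = FALSE)
    space <- kmer_feature_names(space, k)
  }
  stopifnot(is.character(seqs))
  m <- matrix(0, nrow = length(seqs), ncol = length(space$names),
              dimnames = list(names(seqs), space$names))
  for (r in seq_along(seqs)) {
    m[r, ] <- encode_pseudoknc(seqs[r], space, normalize = normalize)
  }
  m
}
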
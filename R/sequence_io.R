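#' Read sequences from FASTA
#'
#' Parses FASTA text into a named character vector of residue strings.
#' Sequences are uppercased and whitespace-stripped; wrapped (multi-line)
#' records are joined. Input order is preserved. Duplicate ids are kept but
#' trigger a warning, since downstream stages key records by position.
#'
#' @param source Path to a FASTA file, or a character scalar containing FASTA
#'   text (recognised by a leading `">"` or an embedded newline). An empty
#'   string yields an empty result.
#'
#' @return Named character vector: names are record ids (the header up to the
#'   first whitespace), values are upper-case residue strings.
#'
#' @seealso [write_fasta()], [filter_valid()]
#' @export
read_fasta <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  path <- source
  if (!file.exists(source) &&
      (startsWith(source, ">") || grepl("\n", source, fixed = TRUE) || !nzchar(source))) {
    path <- tempfile(fileext = ".fa")
    on.exit(unlink(path), add = TRUE)
    writeLines(source, path)
  }
  if (!file.exists(path)) {
    stop("FASTA source not found: ", source, call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA input: ", conditionMessage(e), call. = FALSE)
    }
  )
  if (length(set) == 0L) {
    return(structure(character(0), names = character(0)))
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(gsub("[[:space:]]", "", as.character(set)))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("malformed FASTA input: empty sequence under header(s): ",
         paste(ids[empty], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    warning("duplicate sequence ids: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' Inverse of [read_fasta()]: writing then reading reproduces ids and residues
#' exactly for valid records.
#'
#' @param seqs Named character vector of residue strings (names are ids).
#' @param path Output file path.
#' @param width Line-wrap width for residue lines (default 60).
#'
#' @return Invisibly, the number of bytes written.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs))
  if (length(seqs) > 0L && (is.null(names(seqs)) || any(!nzchar(names(seqs))))) {
    stop("all records need a non-empty id", call. = FALSE)
  }
  lines <- character(0)
  if (length(seqs) > 0L) {
    lines <- unlist(lapply(seq_along(seqs), function(i) {
      s <- seqs[[i]]
      starts <- seq(1L, nchar(s), by = width)
      c(paste0(">", names(seqs)[i]), substring(s, starts, starts + width - 1L))
    }), use.names = FALSE)
  }
  con <- tryCatch(file(path, "wb"), error = function(e) {
    stop("cannot open sink for writing: ", conditionMessage(e), call. = FALSE)
  })
  on.exit(close(con), add = TRUE)
  if (length(lines)) writeLines(lines, con, sep = "\n")
  flush(con)
  invisible(sum(nchar(lines, type = "bytes") + 1L))
}

#' Filter records to a closed alphabet
#'
#' Splits a batch of sequences into records composed entirely of the declared
#' alphabet's symbols and records containing any foreign character.
#' Benchmark curation for virion-protein data conventionally drops sequences
#' with ambiguity or non-standard codes (Z, X, U, B and the like); filtering
#' against the full closed alphabet subsumes that list and also catches J, O,
#' gaps and digits, which downstream encoders cannot represent.
#'
#' @param seqs Named character vector of residue strings.
#' @param alphabet A [alphabet()] object (or its kind as a string).
#'
#' @return A list with elements:
#'   \describe{
#'     \item{kept}{records containing only alphabet symbols, input order kept}
#'     \item{removed}{data.frame with columns `id` and `offending`
#'       (comma-separated set of foreign characters), input order kept}
#'   }
#'   `length(kept) + nrow(removed)` always equals `length(seqs)`, and
#'   filtering is idempotent on `kept`.
#' @export
filter_valid <- function(seqs, alphabet = "protein") {
  alphabet <- as_alphabet(alphabet)
  stopifnot(is.character(seqs))
  if (length(seqs) == 0L) {
    return(list(kept = seqs,
                removed = data.frame(id = character(0), offending = character(0),
                                     stringsAsFactors = FALSE)))
  }
  foreign <- lapply(strsplit(seqs, ""), function(ch) sort(unique(setdiff(ch, alphabet$symbols))))
  bad <- lengths(foreign) > 0L
  list(
    kept = seqs[!bad],
    removed = data.frame(
      id = names(seqs)[bad] %||% character(0),
      offending = vapply(foreign[bad], paste, character(1), collapse = ","),
      stringsAsFactors = FALSE
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a labelled sequence set
#'
#' Two supported layouts: a pair of FASTA files (positives then negatives), or
#' one FASTA plus a two-column tab-separated `id<TAB>label` table with labels
#' in \{0, 1\} (1 = phage virion protein).
#'
#' @param pos Path to the positive-class FASTA, or to the single FASTA when
#'   `labels` is given.
#' @param neg Path to the negative-class FASTA (two-FASTA layout).
#' @param labels Path to a tab-separated id-to-label table (single-FASTA
#'   layout).
#'
#' @return List with `seqs` (named character vector) and `labels` (integer
#'   vector in \{0, 1\}, aligned to `seqs`).
#' @export
read_labeled <- function(pos, neg = NULL, labels = NULL) {
  if (is.null(neg) == is.null(labels)) {
    stop("supply exactly one of `neg` (two-FASTA layout) or `labels` (label table)",
         call. = FALSE)
  }
  if (!is.null(neg)) {
    p <- read_fasta(pos)
    n <- read_fasta(neg)
    return(list(seqs = c(p, n), labels = rep(c(1L, 0L), c(length(p), length(n)))))
  }
  seqs <- read_fasta(pos)
  tab <- utils::read.table(labels, sep = "\t", header = FALSE,
                           col.names = c("id", "label"),
                           colClasses = c("character", "integer"))
  if (!all(tab$label %in% c(0L, 1L))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  m <- match(names(seqs), tab$id)
  if (anyNA(m)) {
    stop("no label for id(s): ", paste(names(seqs)[is.na(m)], collapse = ", "),
         call. = FALSE)
  }
  list(seqs = seqs, labels = tab$label[m])
}
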
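#' Sequence alphabets
#'
#' Construct one of the three closed residue alphabets used throughout the
#' package. Symbol order is fixed: it determines feature-column order in every
#' encoder.
#'
#' @param kind One of `"protein"`, `"dna"`, `"rna"` (case-insensitive).
#'
#' @return An object of class `pvp_alphabet`: a list with elements `kind`
#'   (upper-case string) and `symbols` (ordered character vector; 4 symbols
#'   for nucleic acids, 20 for protein).
#'
#' @examples
#' alphabet("dna")$symbols     # A C G T
#' length(alphabet("protein")$symbols)  # 20
#' @export
alphabet <- function(kind = c("protein", "dna", "rna")) {
  kind <- toupper(match.arg(tolower(kind), c("protein", "dna", "rna")))
  symbols <- switch(kind,
    DNA = c("A", "C", "G", "T"),
    RNA = c("A", "C", "G", "U"),
    PROTEIN = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  )
  structure(list(kind = kind, symbols = symbols), class = "pvp_alphabet")
}

#' @export
print.pvp_alphabet <- function(x, ...) {
  cat(sprintf("<pvp_alphabet> %s: %s\n", x$kind, paste(x$symbols, collapse = "")))
  invisible(x)
}

as_alphabet <- function(x) {
  if (inherits(x, "pvp_alphabet")) return(x)
  if (is.character(x) && length(x) == 1L) return(alphabet(x))
  stop("`alphabet` must be a pvp_alphabet object or one of \"protein\", \"dna\", \"rna\"",
       call. = FALSE)
}
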
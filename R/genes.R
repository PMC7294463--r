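#' Normalize gene symbols
#'
#' Gene-symbol matching throughout the package is case-insensitive: rodent
#' symbols ("Ccl11") and human-style uppercase symbols ("CCL11") refer to the
#' same gene. The canonical form is uppercase; surrounding whitespace is
#' dropped. Alias symbols joined with "/" (e.g. "Ngfr/p75NTR") keep their
#' first token.
#'
#' @param x character vector of gene symbols.
#' @return uppercase canonical symbols, same length as `x`.
#' @export
#' @examples
#' norm_genes(c("Ccl11", "NGF ", "Ngfr/p75NTR"))
norm_genes <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("/.*$", "", x)
  toupper(x)
}

#' Construct a named gene set
#'
#' A gene set is a character vector of unique, case-normalized symbols with a
#' `name` attribute. Most package functions accept plain character vectors and
#' normalize them internally; `gene_set()` makes the normalization explicit.
#'
#' @param members character vector of gene symbols.
#' @param name label for the set.
#' @return character vector of class `gene_set` (unique, uppercase, sorted).
#' @export
gene_set <- function(members, name = "gene_set") {
  members <- sort(unique(norm_genes(members)))
  members <- members[nzchar(members)]
  structure(members, name = name, class = c("gene_set", "character"))
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set '%s': %d genes>\n", attr(x, "name"), length(x)))
  if (length(x)) print(utils::head(unclass(x), 10))
  invisible(x)
}

# internal: stop on duplicated identifiers, naming the duplicates
check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop(sprintf("duplicate %s identifier(s): %s", what,
                 paste(utils::head(dup, 5), collapse = ", ")), call. = FALSE)
  }
  invisible(ids)
}
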
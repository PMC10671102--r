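#' IUPAC nucleotide codes and matching semantics
#'
#' Point heteroplasmies (PHPs) are reported with the two-base IUPAC code for
#' the observed allele pair (e.g. `Y` for a C/T mixture). Forensic haplotype
#' comparison uses two policies: *literal*, where a symbol only matches an
#' identical symbol, and *pattern*, where two symbols match whenever their
#' base expansions intersect (a `Y` matches a `C`, a `T`, or another `Y`).
#'
#' @name iupac
NULL

# expansion sets for the 15 informative IUPAC symbols plus N
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.IUPAC_SYMBOLS <- names(.IUPAC)

#' Expand an IUPAC symbol to its base set
#'
#' @param x single IUPAC symbol.
#' @return Character vector of bases in `{A,C,G,T}`.
#' @export
iupac_expand <- function(x) {
  x <- toupper(x)
  if (length(x) != 1L || is.na(x) || is.null(.IUPAC[[x]])) {
    stop("invalid IUPAC symbol: ", deparse(x))
  }
  .IUPAC[[x]]
}

#' Two-base IUPAC code for an unordered base pair
#'
#' @param b1,b2 distinct bases in `{A,C,G,T}`.
#' @return The degenerate symbol whose expansion is `{b1, b2}`.
#' @export
iupac_code <- function(b1, b2) {
  pair <- sort(toupper(c(b1, b2)))
  hit <- vapply(.IUPAC, function(e) length(e) == 2L && all(e == pair),
                logical(1))
  if (!any(hit)) stop("no two-base IUPAC code for ", b1, "/", b2)
  names(.IUPAC)[hit]
}

#' Compare two IUPAC symbols under a matching policy
#'
#' Literal matching is symbol equality; pattern matching succeeds when the
#' base expansions of the two symbols share at least one base. `N` is
#' treated as missing data by the haplotype comparison layer and should be
#' screened out before calling this predicate; passed directly, it behaves
#' as its full four-base expansion.
#'
#' @param a,b IUPAC symbols.
#' @param policy `"literal"` or `"pattern"`.
#' @return Logical scalar.
#' @examples
#' iupac_match("Y", "C", "pattern")  # TRUE
#' iupac_match("Y", "C", "literal")  # FALSE
#' @export
iupac_match <- function(a, b, policy = c("literal", "pattern")) {
  policy <- match.arg(policy)
  ea <- iupac_expand(a)
  eb <- iupac_expand(b)
  if (policy == "literal") toupper(a) == toupper(b)
  else length(intersect(ea, eb)) > 0L
}

#' Is a symbol ambiguous (more than one base in its expansion)?
#' @param x character vector of IUPAC symbols.
#' @return Logical vector.
#' @export
iupac_is_ambiguous <- function(x) {
  vapply(toupper(x), function(s) {
    e <- .IUPAC[[s]]
    !is.null(e) && length(e) > 1L
  }, logical(1), USE.NAMES = FALSE)
}

# transition partner: A<->G, C<->T
.transition <- function(base) {
  c(A = "G", G = "A", C = "T", T = "C")[[toupper(base)]]
}

# the two transversion partners of a base
.transversions <- function(base) {
  setdiff(c("A", "C", "G", "T"), c(toupper(base), .transition(base)))
}
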
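#' EMPOP-style haplotype notation
#'
#' A haplotype is the ordered set of differences of a sample from the rCRS:
#' substitutions (`263G`), insertions with a 1-based index after the anchor
#' position (`315.1C`; the wildcard index `309.xC` denotes a variable
#' insertion count), and deletions (`8281DEL`, also read as `8281-`). IUPAC
#' two-base codes mark point heteroplasmies (`152Y`). A sample identical to
#' the reference has an empty variant set.
#'
#' @name haplotype-notation
NULL

.DEL <- "DEL"

.empty_variants <- function() {
  data.frame(pos = integer(0), kind = character(0), idx = character(0),
             obs = character(0), ref = character(0), stringsAsFactors = FALSE)
}

#' Construct a haplotype object
#'
#' @param variants data.frame with columns `pos` (integer), `kind`
#'   (`"sub"`, `"ins"`, `"del"`), `idx` (insertion index as character,
#'   `"x"` for the wildcard, `NA` otherwise), `obs` (IUPAC symbol or
#'   `"DEL"`), `ref` (reference base or `NA`).
#' @param sample_id sample identifier.
#' @param range `mtrange` the haplotype covers (default mitogenome).
#' @param coverage_class,lhp_regions,haplogroup optional QC metadata.
#' @return Object of class `mthaplotype`.
#' @export
mt_haplotype <- function(variants = .empty_variants(), sample_id = NA_character_,
                         range = standard_range("mitogenome"),
                         coverage_class = NA_character_,
                         lhp_regions = character(0),
                         haplogroup = NA_character_) {
  v <- .validate_variants(variants)
  structure(list(sample_id = sample_id, variants = v, range = range,
                 coverage_class = coverage_class, lhp_regions = lhp_regions,
                 haplogroup = haplogroup),
            class = "mthaplotype")
}

.validate_variants <- function(v) {
  need <- c("pos", "kind", "idx", "obs")
  if (!all(need %in% names(v))) stop("variant table missing columns")
  if (is.null(v$ref)) v$ref <- NA_character_
  v <- v[, c("pos", "kind", "idx", "obs", "ref")]
  v$pos <- as.integer(v$pos)
  v$obs <- toupper(as.character(v$obs))
  v$kind <- as.character(v$kind)
  v$idx <- as.character(v$idx)
  v$ref <- toupper(as.character(v$ref))
  if (any(v$pos < 1L | v$pos > MT_LENGTH)) stop("variant position outside 1..16569")
  if (!all(v$kind %in% c("sub", "ins", "del"))) stop("bad variant kind")
  bad <- v$kind == "sub" & !(v$obs %in% setdiff(.IUPAC_SYMBOLS, character(0)))
  if (any(bad)) stop("bad substitution symbol: ", paste(v$obs[bad], collapse = ", "))
  if (any(v$kind == "del" & v$obs != .DEL)) stop("deletion must observe DEL")
  if (any(v$kind == "ins" & !(grepl("^[0-9]+$", v$idx) | v$idx == "x"))) {
    stop("insertion index must be a positive integer or 'x'")
  }
  sub_ref_known <- v$kind == "sub" & !is.na(v$ref)
  if (any(sub_ref_known & v$obs == v$ref)) {
    stop("substitution equal to reference base at position ",
         paste(v$pos[sub_ref_known & v$obs == v$ref], collapse = ", "))
  }
  key <- paste(v$pos, v$kind, ifelse(is.na(v$idx), "", v$idx))
  if (anyDuplicated(key)) {
    stop("duplicate variant at ", paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  .sort_variants(v)
}

# order: position, then sub < del < ins, then numeric index with "x" last
.sort_variants <- function(v) {
  kind_rank <- match(v$kind, c("sub", "del", "ins"))
  idx_num <- suppressWarnings(as.numeric(v$idx))
  idx_num[v$idx == "x"] <- Inf
  idx_num[is.na(idx_num) & v$kind != "ins"] <- -1
  v <- v[order(v$pos, kind_rank, idx_num), , drop = FALSE]
  rownames(v) <- NULL
  v
}

#' @export
print.mthaplotype <- function(x, ...) {
  cat(sprintf("<mthaplotype> %s [%s] %d variant(s)%s\n",
              x$sample_id, x$range$name, nrow(x$variants),
              if (!is.na(x$haplogroup)) paste0(" hg=", x$haplogroup) else ""))
  if (nrow(x$variants) > 0) cat(" ", serialize_haplotype(x), "\n")
  invisible(x)
}

#' Number of variants in a haplotype
#' @param x `mthaplotype`.
#' @export
n_variants <- function(x) nrow(x$variants)

# token grammar:   digits[.index]{IUPAC}   |   digits{DEL|-}
.parse_token <- function(token, ref = NULL) {
  t <- toupper(trimws(token))
  m <- regmatches(t, regexec("^([0-9]+)(DEL|-)$", t))[[1]]
  if (length(m)) {
    pos <- as.integer(m[2])
    return(data.frame(pos = pos, kind = "del", idx = NA_character_, obs = .DEL,
                      ref = if (is.null(ref)) NA_character_ else ref_base(ref, pos),
                      stringsAsFactors = FALSE))
  }
  m <- regmatches(t, regexec("^([0-9]+)\\.([0-9]+|X)([ACGTRYSWKMBDHVN])$", t))[[1]]
  if (length(m)) {
    idx <- tolower(m[3])
    if (idx != "x" && as.integer(idx) < 1L) stop("malformed token: ", token)
    return(data.frame(pos = as.integer(m[2]), kind = "ins", idx = idx,
                      obs = m[4], ref = NA_character_, stringsAsFactors = FALSE))
  }
  m <- regmatches(t, regexec("^([0-9]+)([ACGTRYSWKMBDHVN])$", t))[[1]]
  if (length(m)) {
    pos <- as.integer(m[2])
    return(data.frame(pos = pos, kind = "sub", idx = NA_character_, obs = m[3],
                      ref = if (is.null(ref)) NA_character_ else ref_base(ref, pos),
                      stringsAsFactors = FALSE))
  }
  stop("malformed variant token: '", token, "'")
}

#' Parse a whitespace-separated haplotype string
#'
#' @param text variant tokens separated by whitespace; `""` yields the
#'   reference-identical (empty) haplotype.
#' @param range `mtrange`; tokens outside the range are rejected when
#'   `outside = "error"` or dropped with a warning when `outside = "drop"`.
#' @param sample_id sample identifier.
#' @param ref optional `mtreference` used to annotate reference bases.
#' @param outside handling of out-of-range tokens.
#' @return `mthaplotype`.
#' @examples
#' h <- parse_haplotype("263G 315.1C")
#' serialize_haplotype(h)
#' @export
parse_haplotype <- function(text, range = standard_range("mitogenome"),
                            sample_id = NA_character_, ref = NULL,
                            outside = c("error", "drop")) {
  outside <- match.arg(outside)
  tokens <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) {
    return(mt_haplotype(sample_id = sample_id, range = range))
  }
  v <- do.call(rbind, lapply(tokens, .parse_token, ref = ref))
  out <- !in_mt_range(v$pos, range)
  if (any(out)) {
    bad <- paste(tokens[out], collapse = ", ")
    if (outside == "error") stop("token(s) outside range '", range$name, "': ", bad)
    warning("dropping token(s) outside range '", range$name, "': ", bad)
    v <- v[!out, , drop = FALSE]
  }
  mt_haplotype(v, sample_id = sample_id, range = range)
}

.token <- function(v) {
  ifelse(v$kind == "del", paste0(v$pos, .DEL),
         ifelse(v$kind == "ins", paste0(v$pos, ".", v$idx, v$obs),
                paste0(v$pos, v$obs)))
}

#' Serialize a haplotype to canonical EMPOP-style text
#'
#' Tokens are emitted in canonical order (position, then insertion index);
#' `parse_haplotype(serialize_haplotype(h))` reproduces `h`'s variant set.
#'
#' @param h `mthaplotype`.
#' @return Single string (empty for a reference-identical haplotype).
#' @export
serialize_haplotype <- function(h) {
  stopifnot(inherits(h, "mthaplotype"))
  if (nrow(h$variants) == 0L) return("")
  paste(.token(h$variants), collapse = " ")
}

#' Restrict a haplotype to a range
#'
#' Keeps the variants whose positions fall in `range` and records the
#' intersected coverage. Idempotent; restricting to a sub-range never adds
#' variants.
#'
#' @param h `mthaplotype`.
#' @param range `mtrange`.
#' @return `mthaplotype`.
#' @export
restrict_to_range <- function(h, range) {
  stopifnot(inherits(h, "mthaplotype"), inherits(range, "mtrange"))
  keep <- in_mt_range(h$variants$pos, range)
  new_range <- mt_range_intersect(h$range, range, name = range$name)
  if (is.null(new_range)) new_range <- range
  mt_haplotype(h$variants[keep, , drop = FALSE], sample_id = h$sample_id,
               range = new_range, coverage_class = h$coverage_class,
               lhp_regions = h$lhp_regions, haplogroup = h$haplogroup)
}

# ---------------------------------------------------------------------------
# Haplotype file IO: sample_id <TAB> range_name <TAB> tokens
# ---------------------------------------------------------------------------

#' Write haplotypes to a tab-separated text file
#'
#' One sample per line: `sample_id<TAB>range_name<TAB>tokens`.
#'
#' @param hs list of `mthaplotype`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(hs, path) {
  lines <- vapply(hs, function(h) {
    paste(h$sample_id, h$range$name, serialize_haplotype(h), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read haplotypes from a tab-separated text file
#'
#' @param path file written by [write_haplotypes()].
#' @param ref optional `mtreference` for reference-base annotation.
#' @return List of `mthaplotype`.
#' @export
read_haplotypes <- function(path, ref = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L) stop("malformed haplotype line: ", line)
    rng <- tryCatch(standard_range(f[2]),
                    error = function(e) standard_range("mitogenome"))
    parse_haplotype(if (length(f) >= 3L) f[3] else "", range = rng,
                    sample_id = f[1], ref = ref)
  })
}
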
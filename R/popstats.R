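#' Haplotype matching, frequency spectra and forensic statistics
#'
#' Pairwise haplotype comparison over a reporting range under the literal
#' (symbol equality) or pattern (IUPAC expansion overlap) policy, with
#' indels ignored by default; grouping of a sample set into haplotype
#' classes; and the forensic summary statistics computed from the resulting
#' haplotype frequency spectrum: observed random match probability
#' (sum of squared class frequencies), empirical random match probability
#' (fraction of matching distinct sample pairs), and haplotype diversity.
#'
#' @name popstats
NULL

#' Matching policy
#'
#' @param mode `"literal"` (a Y only matches a Y) or `"pattern"` (a Y
#'   matches a C or a T).
#' @param ignore_indels drop insertions and deletions before comparison
#'   (the forensic default).
#' @param range `mtrange` over which to compare.
#' @return Object of class `match_policy`.
#' @export
match_policy <- function(mode = c("literal", "pattern"), ignore_indels = TRUE,
                         range = standard_range("mitogenome")) {
  mode <- match.arg(mode)
  structure(list(mode = mode, ignore_indels = ignore_indels, range = range),
            class = "match_policy")
}

# substitution map of a haplotype restricted to a range; ref column is used
# to fill the implicit state at positions where only the other sample varies
.sub_table <- function(h, range) {
  r <- restrict_to_range(h, range)
  v <- r$variants
  v[v$kind == "sub", c("pos", "obs", "ref"), drop = FALSE]
}

.indel_keys <- function(h, range) {
  r <- restrict_to_range(h, range)
  v <- r$variants
  v <- v[v$kind != "sub", , drop = FALSE]
  # the wildcard insertion index matches any index at the same position
  idx <- ifelse(v$kind == "ins", ifelse(v$idx == "x", "x", v$idx), "")
  sort(paste0(v$pos, ":", v$kind, ":", idx, ":", v$obs))
}

#' Compare two haplotypes under a matching policy
#'
#' After restricting both haplotypes to the policy range (and dropping
#' indels when `ignore_indels`), the substitution maps must cover the same
#' positions and agree at each position under the policy's IUPAC
#' semantics; at positions where only one sample varies, the other sample's
#' state is the reference base. Positions where either symbol is `N` are
#' skipped as missing data.
#'
#' @param h1,h2 `mthaplotype` objects.
#' @param policy `match_policy`.
#' @param ref optional `mtreference` used to resolve reference states when
#'   the variant tables carry no `ref` annotation.
#' @return Logical scalar.
#' @export
haplotypes_match <- function(h1, h2, policy = match_policy(), ref = NULL) {
  if (!policy$ignore_indels) {
    k1 <- .indel_keys(h1, policy$range)
    k2 <- .indel_keys(h2, policy$range)
    if (!.indels_compatible(k1, k2)) return(FALSE)
  }
  s1 <- .sub_table(h1, policy$range)
  s2 <- .sub_table(h2, policy$range)
  pos <- union(s1$pos, s2$pos)
  if (length(pos) == 0L) return(TRUE)
  refs <- rep(NA_character_, length(pos))
  refs[match(s1$pos, pos)] <- s1$ref
  refs[match(s2$pos, pos)] <- ifelse(is.na(refs[match(s2$pos, pos)]),
                                     s2$ref, refs[match(s2$pos, pos)])
  if (!is.null(ref)) refs[is.na(refs)] <- ref_base(ref, pos[is.na(refs)])
  a <- refs; a[match(s1$pos, pos)] <- s1$obs
  b <- refs; b[match(s2$pos, pos)] <- s2$obs
  skip <- (!is.na(a) & a == "N") | (!is.na(b) & b == "N")
  a <- a[!skip]; b <- b[!skip]
  if (any(is.na(a) | is.na(b))) return(FALSE)   # unresolved reference state
  if (policy$mode == "literal") return(all(a == b))
  all(mapply(function(x, y) iupac_match(x, y, "pattern"), a, b))
}

# indel sets compatible: exact equality with the "x" wildcard matching any
# insertion index at the same position/base
.indels_compatible <- function(k1, k2) {
  norm <- function(k) sub("^([0-9]+):ins:[0-9x]+:", "\\1:ins:*:", k)
  w1 <- grepl(":ins:x:", k1); w2 <- grepl(":ins:x:", k2)
  if (any(w1) || any(w2)) return(setequal(norm(k1), norm(k2)))
  setequal(k1, k2)
}

# ---------------------------------------------------------------------------
# Frequency spectra
# ---------------------------------------------------------------------------

#' Haplotype frequency spectrum
#'
#' The multiplicity-to-count map of haplotype classes in a sample: e.g.
#' `c(\`1\` = 746, \`2\` = 51)` means 746 singleton classes and 51 classes
#' seen twice. All forensic statistics are functions of this spectrum.
#'
#' @param sizes integer vector of class sizes (one entry per haplotype
#'   class), or `NULL` when `classes` is given.
#' @param classes named integer vector multiplicity -> number of classes.
#' @return Object of class `freq_spectrum` with fields `n` (sample count)
#'   and `classes`.
#' @export
freq_spectrum <- function(sizes = NULL, classes = NULL) {
  if (is.null(classes)) {
    if (is.null(sizes) || length(sizes) == 0L) stop("empty spectrum")
    tab <- table(as.integer(sizes))
    classes <- stats::setNames(as.integer(tab), names(tab))
  } else {
    classes <- stats::setNames(as.integer(classes), names(classes))
  }
  mult <- as.integer(names(classes))
  if (any(mult < 1L) || any(classes < 0L)) stop("invalid spectrum")
  classes <- classes[classes > 0L]
  mult <- as.integer(names(classes))
  o <- order(mult)
  classes <- classes[o]
  structure(list(n = sum(as.integer(names(classes)) * classes),
                 classes = classes),
            class = "freq_spectrum")
}

#' @export
print.freq_spectrum <- function(x, ...) {
  cat(sprintf("<freq_spectrum> n=%d, %d classes: {%s}\n", x$n,
              sum(x$classes),
              paste(names(x$classes), x$classes, sep = ":", collapse = ", ")))
  invisible(x)
}

#' Group haplotypes into classes under a matching policy
#'
#' Literal mode groups by the exact canonical key (matching is transitive).
#' Pattern mode is not transitive, so classes are built by a deterministic
#' greedy merge: haplotypes are visited in input order and joined to the
#' first existing class *all* of whose members they pattern-match
#' (complete linkage), else they found a new class. An ambiguous symbol
#' therefore bridges only to its first-encountered compatible class: with
#' input order Y, C, T at one position, the C joins the Y but the T then
#' fails against the C member and founds its own class.
#'
#' @param hs list of `mthaplotype`.
#' @param policy `match_policy`.
#' @param ref optional `mtreference` for reference-state resolution.
#' @return List: `spectrum` (`freq_spectrum`), `assignment` (class index
#'   per haplotype), `class_members` (list of member indices).
#' @export
cluster_haplotypes <- function(hs, policy = match_policy(), ref = NULL) {
  n <- length(hs)
  if (n == 0L) stop("no haplotypes to cluster")
  keys <- vapply(hs, function(h) .match_key(h, policy), character(1))
  if (policy$mode == "literal") {
    fac <- factor(keys, levels = unique(keys))
    assignment <- as.integer(fac)
  } else {
    # group literal-identical haplotypes first (any member can stand for
    # the group in pattern comparisons), then complete-linkage greedy merge
    # of the literal classes in order of first appearance
    lit <- factor(keys, levels = unique(keys))
    lit_id <- as.integer(lit)
    lit_rep <- match(levels(lit), keys)       # first haplotype of each class
    amb <- vapply(hs[lit_rep], .has_ambiguity, logical(1), policy = policy)
    classes <- list()                          # member literal-class indices
    class_all_unamb <- logical(0)
    lit_to_class <- integer(length(lit_rep))
    for (c_i in seq_along(lit_rep)) {
      placed <- NA_integer_
      for (k in seq_along(classes)) {
        if (!amb[c_i] && class_all_unamb[k]) next  # literal-distinct: no match
        members <- classes[[k]]
        all_ok <- all(vapply(members, function(m) {
          haplotypes_match(hs[[lit_rep[c_i]]], hs[[lit_rep[m]]], policy,
                           ref = ref)
        }, logical(1)))
        if (all_ok) { placed <- k; break }
      }
      if (is.na(placed)) {
        classes[[length(classes) + 1L]] <- c_i
        class_all_unamb <- c(class_all_unamb, !amb[c_i])
        placed <- length(classes)
      } else {
        classes[[placed]] <- c(classes[[placed]], c_i)
        class_all_unamb[placed] <- class_all_unamb[placed] && !amb[c_i]
      }
      lit_to_class[c_i] <- placed
    }
    assignment <- lit_to_class[lit_id]
  }
  sizes <- tabulate(assignment)
  list(spectrum = freq_spectrum(sizes),
       assignment = assignment,
       class_members = split(seq_len(n), assignment))
}

.match_key <- function(h, policy) {
  r <- restrict_to_range(h, policy$range)
  v <- r$variants
  if (policy$ignore_indels) v <- v[v$kind == "sub", , drop = FALSE]
  if (nrow(v) == 0L) return("")
  paste(.token(.sort_variants(v)), collapse = " ")
}

.has_ambiguity <- function(h, policy) {
  v <- restrict_to_range(h, policy$range)$variants
  v <- v[v$kind == "sub", , drop = FALSE]
  any(iupac_is_ambiguous(v$obs))
}

#' Observed random match probability
#'
#' The probability that two random draws with replacement share a
#' haplotype: the sum of squared class sample frequencies.
#'
#' @param s `freq_spectrum`.
#' @return Fraction in `[0, 1]`.
#' @export
observed_rmp <- function(s) {
  stopifnot(inherits(s, "freq_spectrum"))
  if (s$n < 1L) stop("empty spectrum")
  mult <- as.integer(names(s$classes))
  sum(s$classes * (mult / s$n)^2)
}

#' Empirical random match probability
#'
#' The fraction of distinct (ordered) sample pairs whose haplotypes match.
#'
#' @param s `freq_spectrum`.
#' @return Fraction in `[0, 1]`.
#' @export
empirical_rmp <- function(s) {
  stopifnot(inherits(s, "freq_spectrum"))
  if (s$n < 2L) stop("need at least two samples")
  mult <- as.integer(names(s$classes))
  sum(s$classes * mult * (mult - 1)) / (s$n * (s$n - 1))
}

#' Haplotype diversity (power of discrimination)
#'
#' `(n/(n-1)) * (1 - sum of squared class frequencies)`.
#'
#' @param s `freq_spectrum`.
#' @return Value in `[0, 1]`.
#' @export
haplotype_diversity <- function(s) {
  stopifnot(inherits(s, "freq_spectrum"))
  if (s$n < 2L) stop("need at least two samples")
  (s$n / (s$n - 1)) * (1 - observed_rmp(s))
}

#' Forensic summary statistics from a spectrum
#'
#' @param s `freq_spectrum`.
#' @return List: `n`, `total_haplotypes` (number of classes),
#'   `unique_haplotypes`, `proportion_unique`, `observed_rmp`,
#'   `empirical_rmp`, `haplotype_diversity`.
#' @export
pop_stats <- function(s) {
  stopifnot(inherits(s, "freq_spectrum"))
  total <- sum(s$classes)
  uniq <- if ("1" %in% names(s$classes)) unname(s$classes[["1"]]) else 0L
  list(n = s$n,
       total_haplotypes = total,
       unique_haplotypes = uniq,
       proportion_unique = uniq / total,
       observed_rmp = observed_rmp(s),
       empirical_rmp = empirical_rmp(s),
       haplotype_diversity = haplotype_diversity(s))
}

# ---------------------------------------------------------------------------
# Deduplication of maternal relatives
# ---------------------------------------------------------------------------

#' Remove maternal relatives sharing a haplotype
#'
#' Samples are grouped by shared haplotype with indels ignored and
#' heteroplasmic (ambiguous IUPAC) positions excluded. Within each group,
#' samples connected by the relatedness table form clusters, and only one
#' sample per cluster is retained (the lowest `sample_id`, so removal is
#' deterministic). Samples without a relatedness flag are always retained.
#'
#' @param hs list of `mthaplotype`.
#' @param relatedness data.frame with columns `sample1`, `sample2` (and
#'   optionally `degree`) listing flagged related pairs.
#' @return Filtered list of `mthaplotype`.
#' @export
dedup_related <- function(hs, relatedness) {
  if (is.null(relatedness) || nrow(relatedness) == 0L) return(hs)
  ids <- vapply(hs, function(h) h$sample_id, character(1))
  unknown <- setdiff(unique(c(relatedness$sample1, relatedness$sample2)), ids)
  if (length(unknown)) {
    warning("relatedness table references unknown sample(s): ",
            paste(unknown, collapse = ", "))
  }
  key <- vapply(hs, function(h) {
    v <- h$variants
    v <- v[v$kind == "sub" & !iupac_is_ambiguous(v$obs), , drop = FALSE]
    paste(.token(v), collapse = " ")
  }, character(1))
  drop <- logical(length(hs))
  for (k in unique(key)) {
    members <- which(key == k)
    if (length(members) < 2L) next
    mids <- ids[members]
    # union-find over related pairs within the shared-haplotype group
    parent <- seq_along(members)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    pairs <- relatedness[relatedness$sample1 %in% mids &
                           relatedness$sample2 %in% mids, , drop = FALSE]
    for (j in seq_len(nrow(pairs))) {
      a <- find(match(pairs$sample1[j], mids))
      b <- find(match(pairs$sample2[j], mids))
      if (a != b) parent[b] <- a
    }
    roots <- vapply(seq_along(members), find, integer(1))
    for (r in unique(roots)) {
      cl <- members[roots == r]
      if (length(cl) > 1L) {
        keep <- cl[order(ids[cl])[1]]
        drop[setdiff(cl, keep)] <- TRUE
      }
    }
  }
  hs[!drop]
}

# ---------------------------------------------------------------------------
# Chi-squared test with Yates's continuity correction
# ---------------------------------------------------------------------------

#' Chi-squared test of homogeneity with Yates's correction
#'
#' Continuity-corrected statistic `sum((|O - E| - 0.5)^2 / E)` (the
#' correction is capped at `|O - E|`, as in the standard implementation)
#' with `(r-1)(c-1)` degrees of freedom and an upper-tail chi-squared
#' p-value. Used to compare haplogroup distributions between datasets.
#'
#' @param tab matrix of non-negative counts (datasets x haplogroup bins).
#' @return List: `statistic`, `df`, `p_value`, `expected`.
#' @export
chisq_yates <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("negative counts")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) stop("zero marginal in contingency table")
  E <- outer(rs, cs) / sum(tab)
  corr <- pmin(0.5, abs(tab - E))
  stat <- sum((abs(tab - E) - corr)^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = E)
}
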
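#' Dataset summaries and spectrum reconstruction
#'
#' Table-style summaries of a called dataset (coverage classes, depth and
#' mapped-read means, average VF, heteroplasmy tallies, per-range forensic
#' statistics) and the small arithmetic used to reconstruct a haplotype
#' frequency spectrum from published sharing constraints.
#'
#' @name summarize
NULL

#' Reconstruct a frequency spectrum from sharing constraints
#'
#' Publications often report the top sharing counts exactly (one haplotype
#' seen 7 times, one 6, one 5, five 4) but pool the remainder ("67 other
#' haplotypes seen two or three times") alongside the singleton and total
#' class counts. The doubleton/tripleton split then follows from the linear
#' system `a + b = n_low` and `2a + 3b = n - singletons - sum(known)`,
#' solved here exactly.
#'
#' @param n total sample count.
#' @param known named integer vector: multiplicity -> number of classes for
#'   the exactly-reported sharing classes.
#' @param n_low number of classes pooled over `low_mults`.
#' @param low_mults the two pooled multiplicities (default 2 and 3).
#' @param singletons number of singleton classes.
#' @return `freq_spectrum`.
#' @export
reconstruct_spectrum <- function(n, known, n_low, low_mults = c(2L, 3L),
                                 singletons) {
  known_samples <- sum(as.integer(names(known)) * known)
  remaining <- n - known_samples - singletons
  sol <- solve(rbind(c(1, 1), as.numeric(low_mults)), c(n_low, remaining))
  if (any(sol < 0) || any(abs(sol - round(sol)) > 1e-9)) {
    stop("sharing constraints have no non-negative integer solution")
  }
  sol <- as.integer(round(sol))
  classes <- c(stats::setNames(sol, low_mults), known,
               stats::setNames(singletons, "1"))
  freq_spectrum(classes = classes)
}

#' Summary proportions from count inputs
#'
#' Recomputes the headline dataset proportions from tallies, at the
#' reporting precision used for population summaries (percentages to one
#' decimal, means to one decimal; round-half-even).
#'
#' @param n_samples number of haplotypes in the dataset.
#' @param php_per_haplotype named integer vector: PHP count per haplotype
#'   -> number of haplotypes (haplotypes with zero PHPs may be omitted).
#' @param n_php_transitions number of PHPs that are transitions.
#' @param n_php total number of PHPs.
#' @param n_lhp_haplotypes haplotypes exhibiting length heteroplasmy.
#' @param max_class_size size of the largest shared-haplotype class.
#' @param total_variants total variants across all haplotypes.
#' @return List of raw values plus `percent` (rounded percentages) and
#'   `mean_variants_per_haplotype`.
#' @export
summarize_counts <- function(n_samples,
                             php_per_haplotype = integer(0),
                             n_php_transitions = NA_integer_,
                             n_php = NA_integer_,
                             n_lhp_haplotypes = NA_integer_,
                             max_class_size = NA_integer_,
                             total_variants = NA_integer_) {
  php_counts <- as.integer(names(php_per_haplotype))
  n_with_php <- sum(php_per_haplotype[php_counts > 0])
  single_php <- if ("1" %in% names(php_per_haplotype))
    unname(php_per_haplotype[["1"]]) else 0L
  vals <- list(
    n_samples = n_samples,
    n_php_haplotypes = n_with_php,
    php_haplotype_proportion = n_with_php / n_samples,
    single_php_share = if (n_with_php > 0) single_php / n_with_php else NA_real_,
    php_transition_share = n_php_transitions / n_php,
    lhp_prevalence = n_lhp_haplotypes / n_samples,
    most_common_haplotype_freq = max_class_size / n_samples,
    mean_variants_per_haplotype = total_variants / n_samples
  )
  vals$percent <- list(
    php_haplotypes = round(100 * vals$php_haplotype_proportion, 1),
    single_php_share = round(100 * vals$single_php_share, 1),
    php_transition_share = round(100 * vals$php_transition_share, 1),
    lhp_prevalence = round(100 * vals$lhp_prevalence, 1),
    most_common_haplotype = round(100 * vals$most_common_haplotype_freq, 1)
  )
  vals$mean_variants_per_haplotype_rounded <-
    round(vals$mean_variants_per_haplotype, 1)
  vals
}

# classify a PHP symbol as transition / transversion / other
.php_class <- function(symbol) {
  ifelse(symbol %in% c("R", "Y"), "transition",
         ifelse(symbol %in% c("S", "W", "K", "M"), "transversion", "other"))
}

#' Summarize a called dataset
#'
#' Builds the analysis-metrics and diversity-table analogues for a set of
#' call results and/or haplotypes: coverage-class tallies with mean mapped
#' reads, depth and average VF per class; variants-per-haplotype mean; the
#' PHP-per-haplotype distribution with transition/transversion tallies; LHP
#' region tallies; per-range, per-mode forensic statistics; and the
#' least-squares R-squared of mapped reads against mean depth.
#'
#' @param results list of `mtcall` (may be `NULL` when only haplotypes are
#'   available).
#' @param hs list of `mthaplotype`; defaults to the haplotypes inside
#'   `results`.
#' @param ranges character vector of standard range names for the
#'   statistics table.
#' @param modes matching modes to evaluate.
#' @param ref optional `mtreference`.
#' @return Object of class `mt_report` (a list of summary components).
#' @export
summarize_dataset <- function(results = NULL, hs = NULL,
                              ranges = c("hvs", "cr", "mitogenome"),
                              modes = c("literal", "pattern"),
                              ref = NULL) {
  if (is.null(hs) && !is.null(results)) {
    hs <- lapply(results, function(r) r$haplotype)
  }
  report <- list(n_samples = length(hs %||% list()))
  if (report$n_samples == 0L) {
    return(structure(report, class = "mt_report"))
  }

  if (!is.null(results)) {
    cls <- vapply(results, function(r) r$coverage_class, character(1))
    md <- vapply(results, function(r) r$mean_depth, numeric(1))
    mr <- vapply(results, function(r) r$mapped_reads, numeric(1))
    vfa <- vapply(results, function(r) r$avg_vf_all %||% NA_real_, numeric(1))
    vfn <- vapply(results, function(r) r$avg_vf_no_hp %||% NA_real_, numeric(1))
    by_class <- lapply(split(seq_along(results), cls), function(ix) {
      list(n = length(ix),
           mean_mapped_reads = mean(mr[ix]),
           mean_depth = mean(md[ix]),
           avg_vf_all = mean(vfa[ix], na.rm = TRUE),
           avg_vf_no_hp = mean(vfn[ix], na.rm = TRUE))
    })
    report$coverage <- by_class
    report$overall <- list(n = length(results),
                           mean_mapped_reads = mean(mr),
                           mean_depth = mean(md),
                           avg_vf_all = mean(vfa, na.rm = TRUE),
                           avg_vf_no_hp = mean(vfn, na.rm = TRUE))
    fit <- stats::lm(mr ~ md)
    report$reads_depth_r2 <- summary(fit)$r.squared
    report$n_mixture_flagged <- sum(vapply(results, function(r)
      isTRUE(r$mixture_flag), logical(1)))
  }

  nv <- vapply(hs, n_variants, integer(1))
  report$total_variants <- sum(nv)
  report$mean_variants_per_haplotype <- mean(nv)

  php_symbols <- unlist(lapply(hs, function(h) {
    v <- h$variants
    v$obs[v$kind == "sub" & iupac_is_ambiguous(v$obs) & v$obs != "N"]
  }))
  php_per_hap <- vapply(hs, function(h) {
    v <- h$variants
    sum(v$kind == "sub" & iupac_is_ambiguous(v$obs) & v$obs != "N")
  }, integer(1))
  report$php <- list(
    total = length(php_symbols),
    per_haplotype = table(php_per_hap),
    class_tally = table(factor(.php_class(php_symbols),
                               levels = c("transition", "transversion", "other")))
  )
  lhp_groups <- unlist(lapply(hs, function(h) unique(h$lhp_regions)))
  report$lhp <- list(
    n_haplotypes = sum(vapply(hs, function(h) length(h$lhp_regions) > 0,
                              logical(1))),
    region_tally = if (length(lhp_groups)) table(lhp_groups) else table(character(0))
  )
  report$counts <- summarize_counts(
    n_samples = length(hs),
    php_per_haplotype = stats::setNames(as.integer(report$php$per_haplotype),
                                        names(report$php$per_haplotype)),
    n_php_transitions = unname(report$php$class_tally["transition"]),
    n_php = report$php$total,
    n_lhp_haplotypes = report$lhp$n_haplotypes,
    max_class_size = NA_integer_,   # filled from the diversity table below
    total_variants = report$total_variants
  )

  if (length(hs) >= 2L) {
    rows <- list()
    for (rg in ranges) for (mode in modes) {
      pol <- match_policy(mode, ignore_indels = TRUE, range = standard_range(rg))
      cl <- cluster_haplotypes(hs, pol, ref = ref)
      st <- pop_stats(cl$spectrum)
      rows[[length(rows) + 1L]] <- data.frame(
        range = rg, mode = mode,
        total_haplotypes = st$total_haplotypes,
        unique_haplotypes = st$unique_haplotypes,
        proportion_unique_pct = round(100 * st$proportion_unique, 1),
        observed_rmp_pct = round(100 * st$observed_rmp, 2),
        empirical_rmp_pct = round(100 * st$empirical_rmp, 2),
        haplotype_diversity = round(st$haplotype_diversity, 4),
        stringsAsFactors = FALSE)
      if (rg == "mitogenome" && mode == "literal") {
        report$counts$most_common_haplotype_freq <-
          max(as.integer(names(cl$spectrum$classes))) / length(hs)
      }
    }
    report$diversity_table <- do.call(rbind, rows)
  }
  structure(report, class = "mt_report")
}

#' @export
print.mt_report <- function(x, ...) {
  cat(sprintf("<mt_report> %d samples", x$n_samples))
  if (!is.null(x$mean_variants_per_haplotype)) {
    cat(sprintf(", %.1f variants/haplotype", x$mean_variants_per_haplotype))
  }
  cat("\n")
  if (!is.null(x$diversity_table)) {
    print(x$diversity_table, row.names = FALSE)
  }
  invisible(x)
}
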
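#' Threshold-based mtDNA haplotype calling
#'
#' Converts a per-position read-evidence table into a forensic-quality
#' haplotype. The core rule set: a variant allele is called when its read
#' frequency reaches the 10% minimum variant-frequency (VF) threshold at a
#' position with sufficient read depth; a position with exactly two alleles
#' at or above the threshold is a point heteroplasmy (PHP) and is reported
#' as the two-base IUPAC code; three or more alleles above the threshold
#' are evidence of a mixture. The 10% threshold is what keeps low-level
#' NUMT-derived alleles (typically below 10%) out of the haplotype; calls
#' inside known NUMT hotspot blocks are additionally flagged. In
#' homopolymeric C-stretches, length variation is summarized per region and
#' only the major length molecule is reported; PHP calls at the polyA
#' artifact positions (302, 16,182, 16,183) are suppressed to the major
#' nucleotide.
#'
#' @name caller
NULL

#' Calling configuration
#'
#' @param min_depth minimum read depth for a position to count as covered
#'   (coverage classification threshold).
#' @param fallback_min_depth lower depth floor: positions at or above it are
#'   still genotyped (the re-analysis rule for low-coverage samples);
#'   positions below it are reported as uncovered.
#' @param min_vf minimum variant frequency for calling.
#' @param noise_floor background noise level; hotspot alleles between the
#'   noise floor and `min_vf` count as sub-threshold NUMT signal.
#' @param numt_hotspots list of `c(start, end)` intervals of known NUMT
#'   hotspot blocks.
#' @param homopolymer_regions data.frame as [homopolymer_regions()].
#' @param suppressed_php_positions positions at which PHPs are reported as
#'   the major nucleotide only.
#' @param nearly_complete_max_low_positions most below-depth positions
#'   allowed for the "nearly complete" coverage class.
#' @param mixture_php_cap more than this many multi-allelic (non-hotspot)
#'   positions raises the mixture flag.
#' @param read_length nominal read length used to convert total aligned
#'   bases into a mapped-read count.
#' @return Object of class `call_config`.
#' @export
call_config <- function(min_depth = 100L, fallback_min_depth = 20L,
                        min_vf = 0.10, noise_floor = 0.02,
                        numt_hotspots = list(c(12501L, 13105L),
                                             c(16496L, 16496L)),
                        homopolymer_regions = mitohap::homopolymer_regions(),
                        suppressed_php_positions = c(302L, 16182L, 16183L),
                        nearly_complete_max_low_positions = 4L,
                        mixture_php_cap = 3L,
                        read_length = 151) {
  if (!(0 < noise_floor && noise_floor < min_vf && min_vf < 0.5)) {
    stop("need 0 < noise_floor < min_vf < 0.5")
  }
  if (fallback_min_depth >= min_depth) stop("fallback_min_depth must be < min_depth")
  structure(list(min_depth = as.integer(min_depth),
                 fallback_min_depth = as.integer(fallback_min_depth),
                 min_vf = min_vf, noise_floor = noise_floor,
                 numt_hotspots = numt_hotspots,
                 homopolymer_regions = homopolymer_regions,
                 suppressed_php_positions = as.integer(suppressed_php_positions),
                 nearly_complete_max_low_positions =
                   as.integer(nearly_complete_max_low_positions),
                 mixture_php_cap = as.integer(mixture_php_cap),
                 read_length = read_length),
            class = "call_config")
}

#' Coverage classification from the count of low-depth positions
#'
#' `0` below-threshold positions is `"complete"`, 1 up to the configured
#' maximum (default 4) is `"nearly_complete"`, more is `"incomplete"`.
#'
#' @param n_below number of positions below the minimum depth.
#' @param config `call_config`.
#' @return One of `"complete"`, `"nearly_complete"`, `"incomplete"`.
#' @export
classify_coverage <- function(n_below, config = call_config()) {
  stopifnot(n_below >= 0)
  if (n_below == 0) "complete"
  else if (n_below <= config$nearly_complete_max_low_positions) "nearly_complete"
  else "incomplete"
}

#' Average major-nucleotide frequency over variant positions
#'
#' The haplotype-level QC metric: the mean frequency of the major
#' nucleotide across a haplotype's variant positions. Excluding
#' heteroplasmic positions (PHP positions and LHP regions) it is expected
#' to exceed 98% in clean single-source data.
#'
#' @param vf numeric vector of major-nucleotide frequencies at variant
#'   positions.
#' @param hp logical vector marking heteroplasmy-affected positions.
#' @param exclude_hp drop the marked positions before averaging.
#' @return Mean frequency, or `NA` when no positions remain.
#' @export
average_vf <- function(vf, hp = rep(FALSE, length(vf)), exclude_hp = FALSE) {
  if (exclude_hp) vf <- vf[!hp]
  if (length(vf) == 0L) return(NA_real_)
  mean(vf)
}

.in_intervals <- function(pos, intervals) {
  hit <- rep(FALSE, length(pos))
  for (iv in intervals) hit <- hit | (pos >= iv[1] & pos <= iv[2])
  hit
}

# parse "SEQ:count;SEQ:count" insertion event strings for a set of rows
.parse_ins_events <- function(pileup, rows) {
  empty <- data.frame(pos = integer(0), seq = character(0),
                      count = integer(0), stringsAsFactors = FALSE)
  if (length(rows) == 0L) return(empty)
  out <- lapply(rows, function(r) {
    ev <- strsplit(pileup$ins[r], ";", fixed = TRUE)[[1]]
    ev <- ev[nzchar(ev)]
    if (length(ev) == 0L) return(NULL)
    parts <- strsplit(ev, ":", fixed = TRUE)
    data.frame(pos = pileup$pos[r],
               seq = toupper(vapply(parts, `[`, character(1), 1)),
               count = as.integer(vapply(parts, `[`, character(1), 2)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) empty else res
}

#' Call a single pileup position
#'
#' Applies the per-position calling rule to one row of read evidence:
#' allele frequencies are computed over the position's depth; exactly two
#' bases at or above `min_vf` yield a PHP with the two-base IUPAC symbol
#' and the minor fraction; one base yields that base; three or more mark
#' the position as mixture-indicative (the major base is still reported).
#' Deletions and insertions are called at the same threshold.
#'
#' @param row one-row slice of an `mtpileup` (or a list with fields
#'   `depth`, `A`, `C`, `G`, `T`, `del`, `ins`).
#' @param ref_base reference base at the position.
#' @param config `call_config`.
#' @return List: `major`, `major_freq`, `symbol` (reported base or IUPAC
#'   code, `NA` when the position is reference), `is_php`, `minor_fraction`,
#'   `n_alleles_above`, `deletion`, `insertions` (data.frame `seq`, `freq`),
#'   `below_depth`, `uncovered`, `mixture_indicative`.
#' @export
call_position <- function(row, ref_base, config = call_config()) {
  depth <- row$depth
  if (is.na(depth) || depth == 0L) {
    return(list(major = NA_character_, major_freq = NA_real_,
                symbol = NA_character_, is_php = FALSE,
                minor_fraction = NA_real_, n_alleles_above = 0L,
                deletion = FALSE, insertions = NULL, below_depth = TRUE,
                uncovered = TRUE, mixture_indicative = FALSE))
  }
  counts <- c(A = row$A, C = row$C, G = row$G, T = row$T)
  freqs <- counts / depth
  above <- names(freqs)[freqs >= config$min_vf]
  major <- names(which.max(freqs))
  suppressed <- isTRUE(row$pos %in% config$suppressed_php_positions)
  is_php <- length(above) == 2L && !suppressed
  symbol <- NA_character_
  minor_fraction <- NA_real_
  if (is_php) {
    symbol <- iupac_code(above[1], above[2])
    minor_fraction <- min(freqs[above])
  } else if (major != toupper(ref_base) && major %in% above) {
    symbol <- major
  }
  del_freq <- row$del / depth
  ins <- NULL
  if (!is.null(row$ins) && nzchar(row$ins)) {
    ev <- .parse_ins_events(data.frame(pos = row$pos %||% 0L, ins = row$ins,
                                       stringsAsFactors = FALSE), 1L)
    ev$freq <- ev$count / depth
    ins <- ev[ev$freq >= config$min_vf, c("seq", "freq"), drop = FALSE]
  }
  list(major = major, major_freq = unname(freqs[major]), symbol = symbol,
       is_php = is_php, minor_fraction = unname(minor_fraction),
       n_alleles_above = length(above),
       deletion = del_freq >= config$min_vf, insertions = ins,
       below_depth = depth < config$min_depth,
       uncovered = depth < config$fallback_min_depth,
       mixture_indicative = length(above) >= 3L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Call a full haplotype from a pileup
#'
#' Applies the per-position rule across the mitogenome, assembles the
#' haplotype, applies the major-length-molecule rule in homopolymer
#' regions, suppresses PHPs at the polyA artifact positions, records NUMT
#' hotspot calls and sub-threshold signal, and computes QC metrics
#' (coverage class, average VF with and without heteroplasmic positions,
#' mixture flag).
#'
#' @param pileup `mtpileup` with one row per reference position.
#' @param ref `mtreference`.
#' @param config `call_config`.
#' @return Object of class `mtcall`: fields `haplotype` (`mthaplotype`),
#'   `coverage_class`, `n_below_min_depth`, `uncovered_positions`,
#'   `avg_vf_all`, `avg_vf_no_hp`, `n_php`, `php_positions`, `numt_flags`,
#'   `sub_threshold_numt_signal`, `mixture_flag`,
#'   `n_multiallelic_positions`, `mean_depth`, `mapped_reads`.
#' @export
call_haplotype <- function(pileup, ref, config = call_config()) {
  L <- ref$length
  if (nrow(pileup) != L || !identical(pileup$pos, seq_len(L))) {
    missing <- setdiff(seq_len(L), pileup$pos)
    stop("pileup missing positions: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) " ...")
  }
  depth <- pileup$depth
  refbases <- ref$bases
  callable <- depth >= config$fallback_min_depth
  uncovered <- which(!callable)
  counts <- cbind(A = pileup$A, C = pileup$C, G = pileup$G, T = pileup$T)
  fmat <- counts / ifelse(depth > 0, depth, 1L)
  major_idx <- max.col(fmat, ties.method = "first")
  bases4 <- c("A", "C", "G", "T")
  major <- bases4[major_idx]
  major_freq <- fmat[cbind(seq_len(L), major_idx)]
  above <- fmat >= config$min_vf
  n_above <- rowSums(above)
  n_above[!callable] <- 0L

  hp <- config$homopolymer_regions
  region_id <- rep(NA_integer_, L)
  for (i in seq_len(nrow(hp))) region_id[hp$start[i]:hp$end[i]] <- i
  hotspot <- .in_intervals(seq_len(L), config$numt_hotspots)
  suppressed <- seq_len(L) %in% config$suppressed_php_positions

  vp <- list()   # variant rows accumulator
  add_variant <- function(pos, kind, idx, obs) {
    vp[[length(vp) + 1L]] <<- data.frame(
      pos = pos, kind = kind, idx = idx, obs = obs,
      ref = refbases[pos], stringsAsFactors = FALSE)
  }

  # --- substitutions and PHPs ---------------------------------------------
  sub_rows <- which(callable & n_above == 1L & major != refbases)
  if (length(sub_rows)) {
    add_variant(sub_rows, "sub", NA_character_, major[sub_rows])
  }
  php_positions <- integer(0)
  two_rows <- which(callable & n_above == 2L)
  for (r in two_rows) {
    bs <- bases4[above[r, ]]
    if (suppressed[r]) {
      # polyA artifact: report the major nucleotide only
      if (major[r] != refbases[r]) add_variant(r, "sub", NA_character_, major[r])
      next
    }
    add_variant(r, "sub", NA_character_, iupac_code(bs[1], bs[2]))
    php_positions <- c(php_positions, r)
  }
  multi_rows <- which(callable & n_above >= 3L)
  for (r in multi_rows) {
    if (major[r] != refbases[r]) add_variant(r, "sub", NA_character_, major[r])
  }

  # --- deletions and insertions outside homopolymer regions ---------------
  del_freq <- pileup$del / ifelse(depth > 0, depth, 1L)
  del_rows <- which(callable & del_freq >= config$min_vf & is.na(region_id))
  if (length(del_rows)) add_variant(del_rows, "del", NA_character_, .DEL)

  ins_rows <- which(nzchar(pileup$ins) & callable)
  ev <- .parse_ins_events(pileup, ins_rows)
  ev$freq <- if (nrow(ev)) ev$count / depth[ev$pos] else numeric(0)
  ev_free <- ev[is.na(region_id[ev$pos]) & ev$freq >= config$min_vf, ,
                drop = FALSE]
  if (nrow(ev_free)) {
    for (j in seq_len(nrow(ev_free))) {
      chars <- strsplit(ev_free$seq[j], "")[[1]]
      add_variant(rep(ev_free$pos[j], length(chars)), "ins",
                  as.character(seq_along(chars)), chars)
    }
  }

  # --- homopolymer regions: length molecules ------------------------------
  lhp_groups <- character(0)
  lhp_spans <- integer(0)
  for (i in seq_len(nrow(hp))) {
    span <- hp$start[i]:hp$end[i]
    span <- span[callable[span]]
    if (length(span) == 0L) next
    mol <- c(`0` = NA_real_)    # reference-length molecule filled below
    reg_ev <- ev[ev$pos %in% span, , drop = FALSE]
    seq_by_len <- list()
    if (nrow(reg_ev)) {
      lens <- nchar(reg_ev$seq)
      for (k in sort(unique(lens))) {
        f <- sum(reg_ev$freq[lens == k])
        mol[as.character(k)] <- f
        sel <- reg_ev[lens == k, , drop = FALSE]
        seq_by_len[[as.character(k)]] <- sel$seq[which.max(sel$count)]
      }
    }
    dmax <- max(del_freq[span])
    if (dmax > 0) mol["-1"] <- dmax
    mol["0"] <- max(0, 1 - sum(mol[names(mol) != "0"], na.rm = TRUE))
    mol <- mol[!is.na(mol)]
    if (sum(mol >= config$min_vf) >= 2L) {
      lhp_groups <- c(lhp_groups, hp$group[i])
      lhp_spans <- c(lhp_spans, span)
    }
    major_mol <- names(mol)[which.max(mol)]
    if (major_mol != "0" && mol[major_mol] >= config$min_vf) {
      k <- as.integer(major_mol)
      if (k > 0L) {
        chars <- strsplit(seq_by_len[[major_mol]], "")[[1]]
        add_variant(rep(hp$anchor[i], k), "ins",
                    as.character(seq_len(k)), chars[seq_len(k)])
      } else {
        add_variant(span[which.max(del_freq[span])], "del", NA_character_, .DEL)
      }
    }
  }
  lhp_groups <- unique(lhp_groups)

  # --- NUMT hotspot annotation --------------------------------------------
  nf_pos <- integer(0); nf_allele <- character(0); nf_freq <- numeric(0)
  sub_threshold <- FALSE
  hs_rows <- which(hotspot & callable)
  for (r in hs_rows) {
    alt <- setdiff(bases4, refbases[r])
    fr <- fmat[r, alt]
    called <- fr >= config$min_vf
    if (any(called)) {
      nf_pos <- c(nf_pos, rep(r, sum(called)))
      nf_allele <- c(nf_allele, alt[called])
      nf_freq <- c(nf_freq, unname(fr[called]))
    }
    if (any(fr >= config$noise_floor & fr < config$min_vf)) sub_threshold <- TRUE
  }
  numt_flags <- data.frame(pos = nf_pos, allele = nf_allele, freq = nf_freq,
                           stringsAsFactors = FALSE)

  # --- assemble haplotype and metrics -------------------------------------
  variants <- if (length(vp)) do.call(rbind, vp) else .empty_variants()
  n_below <- sum(depth < config$min_depth)
  coverage_class <- classify_coverage(n_below, config)

  sub_pos <- variants$pos[variants$kind == "sub"]
  ins_anchor <- unique(variants$pos[variants$kind == "ins"])
  del_vpos <- variants$pos[variants$kind == "del"]
  vp_all <- unique(c(sub_pos, php_positions, ins_anchor, del_vpos))
  allele_major_freq <- pmax(major_freq, del_freq)
  hp_mask <- vp_all %in% php_positions | vp_all %in% lhp_spans
  avg_all <- average_vf(allele_major_freq[vp_all])
  avg_nohp <- average_vf(allele_major_freq[vp_all], hp_mask, exclude_hp = TRUE)

  n_multi <- sum(n_above >= 2L & !hotspot & !suppressed)
  haplotype <- mt_haplotype(variants,
                            sample_id = attr(pileup, "sample_id") %||% NA_character_,
                            coverage_class = coverage_class,
                            lhp_regions = lhp_groups)
  res <- structure(list(
    haplotype = haplotype,
    coverage_class = coverage_class,
    n_below_min_depth = n_below,
    uncovered_positions = uncovered,
    avg_vf_all = avg_all,
    avg_vf_no_hp = avg_nohp,
    n_php = length(php_positions),
    php_positions = php_positions,
    numt_flags = numt_flags,
    sub_threshold_numt_signal = sub_threshold,
    n_multiallelic_positions = n_multi,
    mean_depth = mean(depth),
    mapped_reads = sum(as.numeric(depth)) / config$read_length
  ), class = "mtcall")
  res$mixture_flag <- flag_mixture(res, config)
  res
}

#' @export
print.mtcall <- function(x, ...) {
  cat(sprintf("<mtcall> %s: %d variants, %s coverage, %d PHP, avg VF (no HP) %s\n",
              x$haplotype$sample_id, n_variants(x$haplotype),
              x$coverage_class, x$n_php,
              ifelse(is.na(x$avg_vf_no_hp), "NA",
                     sprintf("%.3f", x$avg_vf_no_hp))))
  invisible(x)
}

#' Mixture flag from call metrics
#'
#' A haplotype is flagged as a possible mixture when the number of
#' multi-allelic (non-hotspot) positions exceeds the configured cap (the
#' default of 3 reflects the maximum PHP count seen in single-source
#' mitogenomes) or when the average VF excluding heteroplasmy falls below
#' 98%.
#'
#' @param result `mtcall` or a list with `n_multiallelic_positions` and
#'   `avg_vf_no_hp`.
#' @param config `call_config`.
#' @return Logical.
#' @export
flag_mixture <- function(result, config = call_config()) {
  n_multi <- result$n_multiallelic_positions %||% 0L
  avg <- result$avg_vf_no_hp
  (n_multi > config$mixture_php_cap) ||
    (!is.null(avg) && !is.na(avg) && avg < 0.98)
}
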
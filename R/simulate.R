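#' Synthetic mtDNA population and pileup simulator
#'
#' Generates populations of true haplotypes with a configured haplotype
#' frequency spectrum (a labeled-clade model: every sample in a clade
#' carries the same haplotype) and per-sample read-evidence tables with the
#' statistical structure of WGS-derived mtDNA pileups: wide per-sample mean
#' depth variation, negative-binomial per-position depth, a low per-base
#' miscall rate, point heteroplasmies as two-allele binomial mixtures,
#' length heteroplasmy as mixtures of length molecules in C-stretches, NUMT
#' contamination concentrated in hotspot blocks, and reduced coverage in
#' homopolymer windows.
#'
#' @name simulate
NULL

# SweGen-shaped haplotype sharing spectrum: one haplotype seen 7x, one 6x,
# one 5x, five 4x, sixteen 3x, fifty-one 2x, and 746 singletons (n = 934).
.default_clade_sizes <- function() {
  c(7L, 6L, 5L, rep(4L, 5), rep(3L, 16), rep(2L, 51), rep(1L, 746))
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a ~934-sample WGS population
#' survey: per-sample mean depth log-uniform over 500-3000X, per-position
#' negative-binomial depth with ~10% coefficient of variation, 0.5% per-base
#' miscall rate (background noise well below the 2% noise floor), 21.9% of
#' samples carrying 1-3 point heteroplasmies with minor fractions 10-50%,
#' length heteroplasmy prevalences per homopolymer region matching the
#' observed region tallies (~73% of samples overall), and NUMT contamination
#' in the hotspot blocks at nps 12,501-13,105 and 16,496 that is detectable
#' above 2% in ~40% of samples but held below the 10% calling threshold.
#'
#' @param n_samples number of samples.
#' @param clade_sizes integer vector of clade sizes (must sum to
#'   `n_samples`); each clade shares one haplotype.
#' @param seed integer seed used by [simulate_population()].
#' @param n_mut_mean Poisson mean of substitutions per clade lineage.
#' @param ts_weight probability a lineage substitution is a transition.
#' @param depth_range per-sample mean depth range (log-uniform draw).
#' @param depth_dispersion negative-binomial size parameter for
#'   per-position depth.
#' @param error_rate per-base miscall probability.
#' @param php_count_probs probabilities of 0..3 PHPs per sample.
#' @param php_frac_range minor-fraction range for injected PHPs.
#' @param php_ts_weight probability an injected PHP is a transition pair.
#' @param lhp_group_probs per-region-group probability of length
#'   heteroplasmy.
#' @param numt_blocks list of NUMT blocks, each `list(start, end,
#'   positions)`; contaminating alleles default to the transition partner
#'   of the reference base.
#' @param numt_prevalence fraction of samples with NUMT signal above the
#'   noise floor.
#' @param numt_frac_detectable,numt_frac_background contamination-fraction
#'   ranges for samples with/without detectable NUMT signal.
#' @param dropout_multiplier depth multiplier applied over homopolymer
#'   windows (coverage dropout).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 934L,
                       clade_sizes = NULL,
                       seed = 1L,
                       n_mut_mean = 25,
                       ts_weight = 0.9,
                       depth_range = c(500, 3000),
                       depth_dispersion = 100,
                       error_rate = 0.005,
                       php_count_probs = c(`0` = 729, `1` = 177,
                                           `2` = 25, `3` = 3) / 934,
                       php_frac_range = c(0.10, 0.50),
                       php_ts_weight = 0.767,
                       lhp_group_probs = c(HVS2 = 599, HVS1 = 172, HVS3 = 46,
                                           AC513 = 17, C460 = 4, C960 = 5,
                                           C5899 = 2, C8276 = 2, C356 = 1,
                                           C498 = 1, C7471 = 1) / 934,
                       numt_blocks = NULL,
                       numt_prevalence = 0.4,
                       numt_frac_detectable = c(0.02, 0.08),
                       numt_frac_background = c(0, 0.02),
                       dropout_multiplier = 0.5) {
  if (is.null(clade_sizes)) {
    clade_sizes <- if (n_samples == 934L) .default_clade_sizes()
                   else rep(1L, n_samples)
  }
  clade_sizes <- as.integer(clade_sizes)
  if (sum(clade_sizes) != n_samples) {
    stop("clade sizes must sum to n_samples (", sum(clade_sizes),
         " != ", n_samples, ")")
  }
  if (any(clade_sizes < 1L)) stop("clade sizes must be positive")
  if (error_rate < 0 || error_rate >= 0.5) stop("error_rate out of range")
  if (php_frac_range[1] <= 0 || php_frac_range[2] > 0.5) {
    stop("PHP minor fractions must lie in (0, 0.5]")
  }
  if (numt_frac_detectable[2] >= 1) stop("NUMT fraction must be < 1")
  if (is.null(numt_blocks)) {
    numt_blocks <- list(
      list(start = 12501L, end = 13105L,
           positions = c(12634L, 12705L, 12850L, 13105L)),
      list(start = 16496L, end = 16496L, positions = 16496L)
    )
  }
  structure(list(
    n_samples = as.integer(n_samples), clade_sizes = clade_sizes,
    seed = as.integer(seed), n_mut_mean = n_mut_mean, ts_weight = ts_weight,
    depth_range = depth_range, depth_dispersion = depth_dispersion,
    error_rate = error_rate, php_count_probs = php_count_probs,
    php_frac_range = php_frac_range, php_ts_weight = php_ts_weight,
    lhp_group_probs = lhp_group_probs, numt_blocks = numt_blocks,
    numt_prevalence = numt_prevalence,
    numt_frac_detectable = numt_frac_detectable,
    numt_frac_background = numt_frac_background,
    dropout_multiplier = dropout_multiplier
  ), class = "sim_config")
}

# positions eligible for lineage substitutions and PHPs: outside
# homopolymer windows and away from the polyA-artifact positions that the
# caller suppresses
.mutable_positions <- function(config) {
  hp <- homopolymer_regions()
  excl <- unlist(mapply(seq, hp$start, hp$end, SIMPLIFY = FALSE))
  excl <- c(excl, 302L, 16182L, 16183L)
  setdiff(seq_len(MT_LENGTH), excl)
}

.random_substitutions <- function(n_mut, ref, pool, ts_weight) {
  pos <- sort(sample(pool, n_mut))
  obs <- vapply(pos, function(p) {
    b <- ref$bases[p]
    if (stats::runif(1) < ts_weight) .transition(b)
    else sample(.transversions(b), 1)
  }, character(1))
  data.frame(pos = pos, kind = "sub", idx = NA_character_, obs = obs,
             ref = ref$bases[pos], stringsAsFactors = FALSE)
}

#' Simulate a population of haplotypes with ground truth
#'
#' Draws one distinct haplotype per clade (every sample in a clade carries
#' it, so the realized haplotype frequency spectrum equals the configured
#' clade sizes), then assigns per-sample nuisance features: mean depth, PHPs
#' with positions/minor alleles/fractions, length-heteroplasmy regions with
#' length-molecule mixtures, and a NUMT contamination fraction.
#' Deterministic for a fixed `config$seed`.
#'
#' @param config `sim_config`.
#' @param ref `mtreference` (default [synthetic_reference()]).
#' @return List with `haplotypes` (list of `mthaplotype`) and `truth`
#'   (per-sample ground truth: clade labels, PHP tables, LHP mixtures,
#'   NUMT fractions, mean depths).
#' @export
simulate_population <- function(config = sim_config(), ref = synthetic_reference()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  pool <- .mutable_positions(config)

  # distinct clade haplotypes
  n_clades <- length(config$clade_sizes)
  seen <- character(0)
  clade_haps <- vector("list", n_clades)
  for (k in seq_len(n_clades)) {
    repeat {
      n_mut <- max(1L, stats::rpois(1, config$n_mut_mean))
      v <- .random_substitutions(n_mut, ref, pool, config$ts_weight)
      key <- paste(v$pos, v$obs, collapse = " ")
      if (!key %in% seen) { seen <- c(seen, key); break }
    }
    clade_haps[[k]] <- v
  }

  clade <- rep(seq_len(n_clades), times = config$clade_sizes)
  ids <- sprintf("S%04d", seq_len(n))
  haplotypes <- lapply(seq_len(n), function(i) {
    mt_haplotype(clade_haps[[clade[i]]], sample_id = ids[i])
  })

  mean_depth <- exp(stats::runif(n, log(config$depth_range[1]),
                                 log(config$depth_range[2])))

  php <- vector("list", n)
  for (i in seq_len(n)) {
    n_php <- sample(as.integer(names(config$php_count_probs)), 1,
                    prob = config$php_count_probs)
    if (n_php == 0L) { php[i] <- list(NULL); next }
    avail <- setdiff(pool, haplotypes[[i]]$variants$pos)
    p <- sort(sample(avail, n_php))
    major <- ref$bases[p]
    minor <- vapply(seq_along(p), function(j) {
      if (stats::runif(1) < config$php_ts_weight) .transition(major[j])
      else sample(.transversions(major[j]), 1)
    }, character(1))
    php[[i]] <- data.frame(pos = p, major = major, minor = minor,
                           fraction = stats::runif(n_php,
                                                   config$php_frac_range[1],
                                                   config$php_frac_range[2]),
                           stringsAsFactors = FALSE)
  }

  hp <- homopolymer_regions()
  lhp <- vector("list", n)
  for (i in seq_len(n)) {
    groups <- names(config$lhp_group_probs)[
      stats::runif(length(config$lhp_group_probs)) < config$lhp_group_probs]
    if (length(groups) == 0L) { lhp[i] <- list(NULL); next }
    lhp[[i]] <- lapply(groups, function(g) {
      reg <- hp[hp$group == g, , drop = FALSE]
      reg <- reg[nrow(reg), , drop = FALSE]   # deepest sub-stretch carries it
      minor_total <- stats::runif(1, 0.15, 0.45)
      # one or two minor length molecules, each above the 10% threshold
      if (minor_total >= 0.25 && stats::runif(1) < 0.4) {
        f2 <- stats::runif(1, 0.10, minor_total - 0.10)
        mix <- c(`0` = 1 - minor_total, `1` = minor_total - f2, `2` = f2)
      } else {
        mix <- c(`0` = 1 - minor_total, `1` = minor_total)
      }
      list(group = g, region = reg$region, anchor = reg$anchor, mix = mix)
    })
  }

  detectable <- stats::runif(n) < config$numt_prevalence
  numt_fraction <- ifelse(
    detectable,
    stats::runif(n, config$numt_frac_detectable[1], config$numt_frac_detectable[2]),
    stats::runif(n, config$numt_frac_background[1], config$numt_frac_background[2])
  )

  list(haplotypes = haplotypes,
       truth = list(sample_id = ids, clade = clade, php = php, lhp = lhp,
                    numt_fraction = numt_fraction, mean_depth = mean_depth,
                    clade_haplotypes = clade_haps, config = config))
}

# multinomial split of `errors` reads over the bases != true base
.scatter_errors <- function(counts, true_idx, errors) {
  L <- length(errors)
  remaining <- errors
  slots <- rep(3L, L)
  for (b in 1:4) {
    mask <- true_idx != b & remaining > 0L & slots > 0L
    if (any(mask)) {
      x <- stats::rbinom(sum(mask), remaining[mask], 1 / slots[mask])
      counts[mask, b] <- counts[mask, b] + x
      remaining[mask] <- remaining[mask] - x
    }
    slots[true_idx != b] <- slots[true_idx != b] - 1L
  }
  counts
}

#' Simulate a per-position read-evidence table for one sample
#'
#' At each position, base counts are multinomial around the sample's true
#' allele with `error_rate` miscalls spread over the other bases; PHP
#' positions mix two alleles at the stated minor fraction; length
#' heteroplasmy appears as insertion length-molecule mixtures at the
#' region's anchor position; depth is negative-binomial around
#' `mean_depth`, reduced by the dropout multiplier in homopolymer windows.
#' NUMT contamination is added afterwards with [inject_numt()]. Uses the
#' ambient RNG stream; seed at the call site for reproducibility.
#'
#' @param truth `mthaplotype` of true (homoplasmic) variants.
#' @param config `sim_config`.
#' @param ref `mtreference`.
#' @param mean_depth per-sample mean read depth.
#' @param php optional data.frame (`pos`, `minor`, `fraction`) of point
#'   heteroplasmies (major allele taken from the truth/reference).
#' @param lhp optional list of length-heteroplasmy entries
#'   (`list(region, anchor, mix)` as produced by [simulate_population()]).
#' @param numt_fraction contamination fraction handed to [inject_numt()].
#' @return `mtpileup` data.frame (`pos`, `depth`, `A`, `C`, `G`, `T`,
#'   `del`, `ins`) with a `sample_id` attribute.
#' @export
simulate_pileup <- function(truth, config = sim_config(), ref = synthetic_reference(),
                            mean_depth = 1000, php = NULL, lhp = NULL,
                            numt_fraction = 0) {
  L <- ref$length
  true_base <- ref$bases
  v <- truth$variants
  subs <- v[v$kind == "sub", , drop = FALSE]
  if (nrow(subs)) true_base[subs$pos] <- subs$obs
  del_pos <- v$pos[v$kind == "del"]

  # depth with homopolymer dropout
  mult <- rep(1, L)
  hp <- homopolymer_regions()
  for (i in seq_len(nrow(hp))) {
    mult[hp$start[i]:hp$end[i]] <- config$dropout_multiplier
  }
  depth <- stats::rnbinom(L, size = config$depth_dispersion,
                          mu = mean_depth * mult)

  e <- config$error_rate
  true_idx <- match(true_base, c("A", "C", "G", "T"))
  counts <- matrix(0L, nrow = L, ncol = 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  correct <- stats::rbinom(L, depth, 1 - e)
  counts[cbind(seq_len(L), true_idx)] <- correct
  counts <- .scatter_errors(counts, true_idx, depth - correct)

  del <- integer(L)
  if (length(del_pos)) {
    # reads support the deletion; miscalls land on the four bases
    for (p in del_pos) {
      d <- depth[p]
      nd <- stats::rbinom(1, d, 1 - e)
      err <- d - nd
      eb <- stats::rmultinom(1, err, rep(0.25, 4))[, 1]
      counts[p, ] <- as.integer(eb)
      del[p] <- nd
    }
  }

  if (!is.null(php) && nrow(php)) {
    for (j in seq_len(nrow(php))) {
      p <- php$pos[j]
      d <- depth[p]
      major <- true_base[p]
      minor <- php$minor[j]
      n_minor <- stats::rbinom(1, d, php$fraction[j])
      n_major <- d - n_minor
      maj_c <- stats::rbinom(1, n_major, 1 - e)
      min_c <- stats::rbinom(1, n_minor, 1 - e)
      row <- integer(4); names(row) <- c("A", "C", "G", "T")
      row[major] <- maj_c
      row[minor] <- row[minor] + min_c
      rest <- setdiff(c("A", "C", "G", "T"), c(major, minor))
      err <- d - maj_c - min_c
      e1 <- stats::rbinom(1, err, 0.5)
      row[rest[1]] <- row[rest[1]] + e1
      row[rest[2]] <- row[rest[2]] + (err - e1)
      counts[p, ] <- as.integer(row)
    }
  }

  ins <- rep("", L)
  # homoplasmic insertions carried by the truth haplotype
  ins_v <- v[v$kind == "ins", , drop = FALSE]
  if (nrow(ins_v)) {
    for (p in unique(ins_v$pos)) {
      at <- ins_v[ins_v$pos == p, , drop = FALSE]
      idx <- ifelse(at$idx == "x", 1L, as.integer(at$idx))
      seq <- paste(at$obs[order(idx)], collapse = "")
      n_ins <- stats::rbinom(1, depth[p], 1 - e)
      ins[p] <- paste0(seq, ":", n_ins)
    }
  }
  # length-heteroplasmy mixtures at region anchors
  if (!is.null(lhp) && length(lhp)) {
    for (entry in lhp) {
      p <- entry$anchor
      mix <- entry$mix
      n_mol <- stats::rmultinom(1, depth[p], mix)[, 1]
      lens <- as.integer(names(mix))
      parts <- character(0)
      for (j in seq_along(lens)) {
        if (lens[j] > 0L && n_mol[j] > 0L) {
          parts <- c(parts, paste0(strrep("C", lens[j]), ":", n_mol[j]))
        }
      }
      prev <- if (nzchar(ins[p])) strsplit(ins[p], ";", fixed = TRUE)[[1]] else character(0)
      ins[p] <- paste(c(prev, parts), collapse = ";")
    }
  }

  pu <- data.frame(pos = seq_len(L), depth = as.integer(depth),
                   A = counts[, "A"], C = counts[, "C"],
                   G = counts[, "G"], T = counts[, "T"],
                   del = del, ins = ins, stringsAsFactors = FALSE)
  class(pu) <- c("mtpileup", "data.frame")
  attr(pu, "sample_id") <- truth$sample_id
  if (numt_fraction > 0) {
    pu <- inject_numt(pu, config$numt_blocks, numt_fraction, ref)
  }
  pu
}

#' Inject NUMT contamination into a pileup
#'
#' Within each hotspot block, reads carrying the NUMT allele are added at
#' the block's positions so that the allele's expected frequency equals the
#' contamination fraction `fraction`; depth increases accordingly. With
#' `fraction = 0` the pileup is returned unchanged.
#'
#' @param pileup `mtpileup`.
#' @param numt_blocks list of blocks `list(start, end, positions,
#'   [alleles])`; `alleles` defaults to the transition partner of the
#'   reference base at each position.
#' @param fraction contamination fraction in `[0, 1)`.
#' @param ref `mtreference`.
#' @return Modified `mtpileup`.
#' @export
inject_numt <- function(pileup, numt_blocks, fraction, ref = synthetic_reference()) {
  if (fraction < 0 || fraction >= 1) stop("NUMT fraction must be in [0, 1)")
  if (fraction == 0) return(pileup)
  for (block in numt_blocks) {
    if (block$start < 1L || block$end > ref$length) {
      stop("NUMT block outside reference")
    }
    alleles <- block$alleles
    if (is.null(alleles)) {
      alleles <- vapply(block$positions, function(p) .transition(ref$bases[p]),
                        character(1))
    }
    for (j in seq_along(block$positions)) {
      p <- block$positions[j]
      add <- as.integer(round(fraction / (1 - fraction) * pileup$depth[p]))
      pileup[[alleles[j]]][p] <- pileup[[alleles[j]]][p] + add
      pileup$depth[p] <- pileup$depth[p] + add
    }
  }
  pileup
}

#' Write a pileup to TSV
#'
#' Columns: `position`, `depth`, `count_A`, `count_C`, `count_G`,
#' `count_T`, `count_del`, `insertions` (semicolon-separated `SEQ:count`
#' events, `.` when none).
#'
#' @param pileup `mtpileup`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(pileup, path) {
  out <- data.frame(position = pileup$pos, depth = pileup$depth,
                    count_A = pileup$A, count_C = pileup$C,
                    count_G = pileup$G, count_T = pileup$T,
                    count_del = pileup$del,
                    insertions = ifelse(nzchar(pileup$ins), pileup$ins, "."),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pileup TSV written by [write_pileup()]
#' @param path input path.
#' @param sample_id sample identifier to attach.
#' @return `mtpileup`.
#' @export
read_pileup <- function(path, sample_id = NA_character_) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "depth", "count_A", "count_C", "count_G", "count_T",
            "count_del", "insertions")
  if (!all(need %in% names(raw))) stop("malformed pileup TSV: ", path)
  pu <- data.frame(pos = as.integer(raw$position), depth = as.integer(raw$depth),
                   A = as.integer(raw$count_A), C = as.integer(raw$count_C),
                   G = as.integer(raw$count_G), T = as.integer(raw$count_T),
                   del = as.integer(raw$count_del),
                   ins = ifelse(raw$insertions == ".", "", raw$insertions),
                   stringsAsFactors = FALSE)
  class(pu) <- c("mtpileup", "data.frame")
  attr(pu, "sample_id") <- sample_id
  pu
}
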
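#' Pipeline orchestration: simulate, call, summarize
#'
#' A thin, reproducible driver over the package's stages. Every run writes
#' a manifest (seed, configuration, package version) sufficient to
#' reproduce its outputs byte-identically; no timestamps are embedded.
#'
#' @name pipeline
NULL

#' Run the simulate -> call -> stats pipeline
#'
#' Simulates a population under `config`, writes the true haplotypes,
#' simulates and calls pileups for the first `n_pileups` samples, writes a
#' QC table of per-sample call metrics, computes the per-range forensic
#' statistics table over all true haplotypes, and writes a JSON report plus
#' a manifest. Rerunning with the same manifest inputs reproduces identical
#' files.
#'
#' @param out_dir output directory (created if needed).
#' @param config `sim_config`; its `seed` drives all randomness.
#' @param n_pileups number of samples for which read-evidence tables are
#'   simulated and re-called (the full population's truth is always
#'   summarized).
#' @param call_cfg `call_config`.
#' @param ref `mtreference`.
#' @return Invisible list of written file paths plus the in-memory report.
#' @export
run_pipeline <- function(out_dir, config = sim_config(), n_pileups = 25L,
                         call_cfg = call_config(), ref = synthetic_reference()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pop <- simulate_population(config, ref)
  truth <- pop$truth

  hap_path <- file.path(out_dir, "haplotypes_true.tsv")
  write_haplotypes(pop$haplotypes, hap_path)

  n_pileups <- min(n_pileups, config$n_samples)
  qc <- vector("list", n_pileups)
  called <- vector("list", n_pileups)
  for (i in seq_len(n_pileups)) {
    pu <- simulate_pileup(pop$haplotypes[[i]], config, ref,
                          mean_depth = truth$mean_depth[i],
                          php = truth$php[[i]], lhp = truth$lhp[[i]],
                          numt_fraction = truth$numt_fraction[i])
    res <- call_haplotype(pu, ref, call_cfg)
    called[[i]] <- res
    qc[[i]] <- data.frame(
      sample_id = truth$sample_id[i],
      coverage_class = res$coverage_class,
      n_below_min_depth = res$n_below_min_depth,
      mean_depth = round(res$mean_depth, 1),
      mapped_reads = round(res$mapped_reads, 1),
      avg_vf_all = round(res$avg_vf_all %||% NA_real_, 4),
      avg_vf_no_hp = round(res$avg_vf_no_hp %||% NA_real_, 4),
      n_php = res$n_php,
      lhp_regions = paste(res$haplotype$lhp_regions, collapse = ","),
      numt_flagged = nrow(res$numt_flags) > 0,
      sub_threshold_numt = res$sub_threshold_numt_signal,
      mixture_flag = res$mixture_flag,
      haplotype = serialize_haplotype(res$haplotype),
      stringsAsFactors = FALSE)
  }
  qc_path <- file.path(out_dir, "qc.tsv")
  utils::write.table(do.call(rbind, qc), qc_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  report <- summarize_dataset(results = called, hs = pop$haplotypes, ref = ref)
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(list(
    n_samples = report$n_samples,
    mean_variants_per_haplotype = report$mean_variants_per_haplotype,
    spectrum = as.list(cluster_haplotypes(
      pop$haplotypes, match_policy("literal"))$spectrum$classes),
    diversity_table = report$diversity_table
  ), report_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(
    package = "mitohap",
    version = as.character(utils::packageVersion("mitohap")),
    seed = config$seed,
    n_samples = config$n_samples,
    n_pileups = n_pileups,
    clade_sizes = config$clade_sizes,
    error_rate = config$error_rate,
    depth_range = config$depth_range,
    min_depth = call_cfg$min_depth,
    min_vf = call_cfg$min_vf,
    outputs = c("haplotypes_true.tsv", "qc.tsv", "report.json")
  ), manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(paths = c(haplotypes = hap_path, qc = qc_path,
                           report = report_path, manifest = manifest_path),
                 report = report, results = called, population = pop))
}
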
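# End-to-end orchestration: simulate (or load) -> adjust & select ->
# single-variant scan -> burden grid + C-alpha -> LD/tags -> report
# bundle with a run manifest.

#' Descriptive variant counts
#'
#' Counts variants by stratum x functional class x rarity x novelty,
#' using the complete-case MAF within each stratum's selected subjects
#' (variants unobserved in a stratum are reported under rarity
#' `"absent"`).
#'
#' @param gm a [genotype_matrix].
#' @param annotations annotation data.frame aligned with
#'   `variant_ids(gm)`.
#' @param cohort selected cohort data.frame; when `NULL` all subjects are
#'   used.
#' @param maf_threshold rarity boundary.
#' @return data.frame of counts.
#' @export
summarize_counts <- function(gm, annotations, cohort = NULL,
                             maf_threshold = 0.05) {
  out <- list()
  for (s in sort(unique(gm$stratum))) {
    subj <- if (is.null(cohort)) NULL else
      cohort$subject_id[cohort$stratum == s &
                          cohort$group %in% c("hyper", "hypo")]
    d <- minor_dosage(gm, s, subjects = subj)
    maf <- apply(d, 2, function(x)
      if (all(is.na(x))) NA_real_ else compute_maf(x))
    rarity <- ifelse(is.na(maf) | maf == 0, "absent",
                     classify_rarity(pmin(maf, 0.5), maf_threshold))
    tab <- as.data.frame(table(
      func_class = annotations$func_class,
      rarity = rarity,
      novel = annotations$novel), stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0, ]
    tab$stratum <- s
    out[[s]] <- tab[, c("stratum", "func_class", "rarity", "novel", "Freq")]
  }
  res <- do.call(rbind, out)
  names(res)[names(res) == "Freq"] <- "n"
  rownames(res) <- NULL
  res
}

#' Run the full extreme-phenotype association pipeline
#'
#' Orchestrates one reproducible run on a simulated cohort: generate the
#' cohort, covariate-adjust and select extremes, then per ancestry
#' stratum run the MAF-stratified single-variant scan (with signed
#' -log10 p and a Bonferroni threshold over the tested variants), the
#' burden-test grid (CMC rare / WS rare / WS all x functional classes),
#' the C-alpha test on all observed exonic variants, and LD estimation
#' with greedy tag-SNP selection over the observed synonymous variants.
#' All tables plus a JSON manifest (configuration echo, seed, per-stage
#' record counts, output digests) are written to `out_dir`; a rerun with
#' the same seed and configuration is byte-identical.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed controlling the whole run.
#' @param n_permutations permutation count for WS / C-alpha.
#' @param r2_threshold tag-SNP coverage threshold.
#' @return (invisibly) list with the in-memory results: `cohort`,
#'   `selected`, `scan`, `burden`, `calpha`, `tags`, `counts`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, seed = 1,
                         n_permutations = 2000, r2_threshold = 0.7) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_cohort(config, seed = seed)
  gm <- sim$gm
  ann <- sim$annotations

  cohort <- adjust_cohort(sim$cohort)
  cohort <- select_extremes(cohort, quartile = config$quartile)
  selected <- cohort[cohort$group %in% c("hyper", "hypo"), ]
  strata <- sort(unique(gm$stratum))

  scan <- list(); burden <- list(); calpha <- list()
  tags <- list(); ld_mats <- list()
  for (s in strata) {
    sc <- single_variant_scan(gm, cohort, s)
    tested <- !is.na(sc$p_value)
    bf <- bonferroni_threshold(0.05, max(sum(tested), 1))
    sc$signed_mlog10p <- NA_real_
    sc$signed_mlog10p[tested] <- signed_neglog10(sc$p_value[tested],
                                                 sc$direction[tested])
    sc$bonferroni <- bf$threshold
    sc$func_class <- ann$func_class
    sc$rsid <- ann$rsid
    scan[[s]] <- sc

    cfg <- burden_config(n_permutations = n_permutations,
                         rng_seed = seed + match(s, strata) * 1000L)
    burden[[s]] <- burden_suite(gm, ann, cohort, s, config = cfg)

    d_sel <- minor_dosage(gm, s, subjects = selected$subject_id[
      selected$stratum == s])
    exonic <- which(ann$func_class %in% c("missense", "synonymous"))
    seen <- exonic[colSums(d_sel[, exonic, drop = FALSE], na.rm = TRUE) > 0]
    ca <- c_alpha_test(d_sel[, seen, drop = FALSE],
                       selected$group[selected$stratum == s] == "hyper",
                       burden_config(n_permutations = n_permutations,
                                     rng_seed = seed + 77L))
    calpha[[s]] <- data.frame(stratum = s, n_variants = ca$n_variants,
                              statistic = ca$statistic, z = ca$z,
                              p_permutation = ca$p_value,
                              p_analytic = ca$p_analytic)

    syn <- which(ann$func_class == "synonymous")
    syn <- syn[colSums(d_sel[, syn, drop = FALSE], na.rm = TRUE) > 0]
    if (length(syn) >= 2) {
      lm_ <- ld_matrix(d_sel[, syn, drop = FALSE])
      ld_mats[[s]] <- lm_$r2
      maf_syn <- apply(d_sel[, syn, drop = FALSE], 2, compute_maf)
      ts <- greedy_tags(lm_$r2, r2_threshold, maf = maf_syn,
                        pos = ann$pos[syn])
      tags[[s]] <- data.frame(stratum = s, variant = names(ts$coverage),
                              tag = unname(ts$coverage))
    }
  }

  counts <- summarize_counts(gm, ann, cohort)

  # write the bundle
  paths <- c(selection = "selection.tsv", counts = "counts.tsv")
  utils::write.table(selected[, c("subject_id", "stratum", "group",
                                  "resid_col", "resid_epi", "resid_adp")],
                     file.path(out_dir, "selection.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(counts, file.path(out_dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (s in strata) {
    write_results_table(scan[[s]],
                        file.path(out_dir, paste0("scan_", s, ".tsv")))
    write_results_table(burden[[s]],
                        file.path(out_dir, paste0("burden_", s, ".tsv")))
    write_results_table(calpha[[s]],
                        file.path(out_dir, paste0("calpha_", s, ".tsv")))
    if (!is.null(tags[[s]]))
      utils::write.table(tags[[s]],
                         file.path(out_dir, paste0("tags_", s, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(ld_mats[[s]]))
      utils::write.table(round(ld_mats[[s]], 6),
                         file.path(out_dir, paste0("ld_r2_", s, ".tsv")),
                         sep = "\t", quote = FALSE)
  }

  files <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    seed = seed,
    n_permutations = n_permutations,
    r2_threshold = r2_threshold,
    config = config[!vapply(config, is.function, logical(1))],
    n_subjects_simulated = nrow(cohort),
    n_selected = nrow(selected),
    n_hyper = sum(selected$group == "hyper"),
    n_hypo = sum(selected$group == "hypo"),
    n_variants = ncol(gm$dosage),
    missing_rate_realized = mean(is.na(gm$dosage)),
    versions = list(package = as.character(utils::packageVersion("extremevar")),
                    r = paste(R.version$major, R.version$minor, sep = ".")),
    outputs = as.list(stats::setNames(tools::md5sum(files),
                                      basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, selected = selected, scan = scan,
                 burden = burden, calpha = calpha, tags = tags,
                 counts = counts, manifest = manifest))
}
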
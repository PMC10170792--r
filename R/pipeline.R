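#' Default pipeline configuration
#'
#' A synthetic quickstart: simulate a small admixed population, run QC,
#' build exact-count SNP/INDEL panels, correct phenotypes, estimate
#' heritability per panel and cross-validate GBLUP/MultiBLUP.
#'
#' @param out_dir output directory.
#' @return a nested configuration list (YAML-serialisable).
#' @export
default_config <- function(out_dir = tempfile("wgsblup_run")) {
  list(
    seed = 1L,
    out_dir = out_dir,
    simulate = list(n_individuals = 300L, n_snp = 5000L, n_indel = 500L,
                    n_subpop = 3L, fst = 0.1, block_size = 20L,
                    within_block_corr = 0.7, missing_rate = 0.01),
    trait = list(h2_snp = 0.3, h2_indel = 0.05,
                 n_causal_snp = 150L, n_causal_indel = 25L),
    traits = "trait",
    adjust_method = "fixed_only",
    qc = list(min_call_rate = 0.9, min_maf = 0.01),
    panels = list(densities = c(500L, 2000L), ld_r2 = numeric(0)),
    models = c("gblup", "multiblup"),
    cv = list(k = 5L, reps = 2L, refit_variances = FALSE),
    structure = FALSE)
}

validate_config <- function(cfg) {
  if (is.null(cfg$seed)) stop("config needs a seed")
  if (is.null(cfg$out_dir)) stop("config needs out_dir")
  if (!is.null(cfg$cv) && cfg$cv$k < 2) stop("cv k must be >= 2")
  if (!is.null(cfg$panels) && any(cfg$panels$densities <= 0))
    stop("panel densities must be positive")
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    stop("config needs either a simulate block or input paths")
  if (!is.null(cfg$inputs)) {
    for (p in unlist(cfg$inputs))
      if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  invisible(cfg)
}

#' Run the full genomic-prediction pipeline
#'
#' Executes QC, panel construction, phenotype correction, per-panel GRM and
#' REML heritability, and cross-validated GBLUP/MultiBLUP accuracy/bias,
#' writing tab-separated result tables plus the resolved configuration
#' (stamped with a config hash and the root seed) to `out_dir`. All
#' randomness derives from the root seed, so a rerun with the same config
#' is byte-identical. Progress is logged to stderr; results go to files
#' only.
#'
#' @param config a configuration list (see [default_config()]) or the path
#'   of a YAML file holding one.
#' @return invisibly, a list with the in-memory results (`h2_table`,
#'   `cv_summary`, `cv_rounds`, `qc_report`, `out_dir`).
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(config$out_dir %||% tempfile("wgsblup_run")),
                           config)
  validate_config(cfg)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(...) message("[wgsblup] ", ...)

  # --- data ----------------------------------------------------------------
  if (!is.null(cfg$inputs)) {
    stage("reading genotypes")
    gm <- if (!is.null(cfg$inputs$vcf)) read_vcf(cfg$inputs$vcf)
          else read_dosage(cfg$inputs$dosage, panel = cfg$inputs$panel)
    pheno <- read_pheno(cfg$inputs$pheno)
  } else {
    stage("simulating genotypes (n=", cfg$simulate$n_individuals,
          ", m=", cfg$simulate$n_snp + cfg$simulate$n_indel, ")")
    scfg <- do.call(sim_config, c(cfg$simulate[setdiff(names(cfg$simulate), "seed")],
                                  list(seed = cfg$seed)))
    sim <- simulate_genotypes(scfg)
    gm <- sim$gm
    tcfg <- do.call(trait_config, c(cfg$trait[setdiff(names(cfg$trait), "seed")],
                                    list(seed = cfg$seed + 1L)))
    ph <- simulate_phenotypes(gm, tcfg, trait_name = cfg$traits[1])
    pheno <- ph$pheno
    write_pheno(ph$truth$true_breeding_values,
                file.path(out, "truth_breeding_values.tsv"))
  }

  # --- QC ------------------------------------------------------------------
  gm_qc <- qc_filter(gm, cfg$qc$min_call_rate, cfg$qc$min_maf)
  qc_rep <- attr(gm_qc, "qc_report")
  stage("QC: ", qc_rep[["n_kept"]], "/", qc_rep[["n_input"]], " variants kept")
  writeLines(paste(names(qc_rep), qc_rep, sep = "\t"),
             file.path(out, "qc_report.tsv"))

  # --- panels + GRMs -------------------------------------------------------
  v <- gm_qc$variants
  panel_grms <- list()   # label -> list(snp = grm, indel = grm or NULL)
  dens <- sort(cfg$panels$densities)
  for (i in seq_along(dens)) {
    d <- dens[i]
    lab <- format(d, scientific = FALSE, trim = TRUE)
    snp_ids <- v$variant_id[v$type == "SNP"]
    if (d > length(snp_ids))
      stop("panel stage: density ", d, " exceeds ", length(snp_ids), " SNPs")
    psnp <- thin_variants(as_variant_panel(v[v$type == "SNP", ]),
                          mode = "exact", count = d, seed = cfg$seed + 10L + i)
    write_panel(psnp, file.path(out, paste0("panel_snp_", lab, ".tsv")))
    g_snp <- compute_grm(subset_geno(gm_qc, variants = psnp$variant_id))
    g_ind <- NULL
    n_indel <- sum(v$type == "INDEL")
    if (n_indel > 0) {
      d_i <- min(d, n_indel)
      pind <- thin_variants(as_variant_panel(v[v$type == "INDEL", ]),
                            mode = "exact", count = d_i,
                            seed = cfg$seed + 100L + i)
      write_panel(pind, file.path(out, paste0("panel_indel_", lab, ".tsv")))
      g_ind <- compute_grm(subset_geno(gm_qc, variants = pind$variant_id))
    }
    panel_grms[[lab]] <- list(snp = g_snp, indel = g_ind)
    stage("panel ", lab, ": GRM on ", g_snp$n_markers, " SNPs",
          if (!is.null(g_ind)) paste0(" + ", g_ind$n_markers, " INDELs"))
  }
  for (r2 in cfg$panels$ld_r2) {
    lab <- paste0("ld", r2)
    pp <- ld_prune(gm_qc, r2_threshold = r2)
    pp <- as_variant_panel(pp[pp$type == "SNP", ])
    write_panel(pp, file.path(out, paste0("panel_", lab, ".tsv")))
    panel_grms[[lab]] <- list(
      snp = compute_grm(subset_geno(gm_qc, variants = pp$variant_id)),
      indel = NULL)
    stage("panel ", lab, ": ", nrow(pp), " LD-pruned SNPs")
  }

  # --- corrected phenotypes ------------------------------------------------
  full_grm <- if (cfg$adjust_method == "animal_model")
    compute_grm(gm_qc) else NULL
  yc_list <- lapply(cfg$traits, function(tr)
    adjust_phenotypes(pheno, tr, method = cfg$adjust_method, grm = full_grm))
  names(yc_list) <- cfg$traits
  yc_tab <- pheno
  for (tr in cfg$traits)
    yc_tab[[paste0(tr, "_Yc")]] <- as.numeric(yc_list[[tr]][pheno$id])
  write_pheno(yc_tab, file.path(out, "phenotypes_corrected.tsv"))
  stage("corrected phenotypes (", cfg$adjust_method, ") for ",
        length(cfg$traits), " trait(s)")

  # --- heritability profile ------------------------------------------------
  h2_rows <- list()
  for (tr in cfg$traits) {
    snp_grms <- lapply(panel_grms, `[[`, "snp")
    prof <- h2_profile(yc_list[[tr]], snp_grms)
    prof <- cbind(trait = tr, variant_type = "SNP", prof)
    h2_rows[[tr]] <- prof
  }
  h2_table <- do.call(rbind, h2_rows)
  write_tsv(h2_table, file.path(out, "h2_table.tsv"))
  stage("heritability table written (", nrow(h2_table), " rows)")

  # --- cross-validation ----------------------------------------------------
  cv_sum <- list(); cv_rounds <- list()
  for (tr in cfg$traits) {
    yc <- yc_list[[tr]]
    for (lab in names(panel_grms)) {
      pg <- panel_grms[[lab]]
      runs <- list()
      if ("gblup" %in% cfg$models)
        runs$gblup <- list(grms = pg$snp, model = "gblup",
                           variant_type = "SNP")
      if ("multiblup" %in% cfg$models && !is.null(pg$indel))
        runs$multiblup <- list(grms = list(f = pg$indel, r = pg$snp),
                               model = "multiblup",
                               variant_type = "SNP+INDEL")
      for (rn in names(runs)) {
        r <- runs[[rn]]
        cv <- cross_validate(yc, r$grms, model = r$model,
                             k = cfg$cv$k, reps = cfg$cv$reps,
                             seed = cfg$seed,
                             refit_variances = isTRUE(cfg$cv$refit_variances))
        key <- data.frame(trait = tr, model = r$model,
                          variant_type = r$variant_type, panel = lab)
        cv_sum[[paste(tr, lab, rn)]] <- cbind(key, cv$summary)
        cv_rounds[[paste(tr, lab, rn)]] <- cbind(key, cv$rounds)
        stage("CV ", tr, "/", lab, "/", r$model,
              sprintf(": accuracy %.3f, bias %.3f",
                      cv$summary$mean_accuracy, cv$summary$mean_bias))
      }
    }
  }
  cv_summary <- do.call(rbind, cv_sum)
  cv_round_tab <- do.call(rbind, cv_rounds)
  write_tsv(cv_summary, file.path(out, "cv_summary.tsv"))
  write_tsv(cv_round_tab, file.path(out, "cv_rounds.tsv"))

  # --- structure diagnostics ----------------------------------------------
  if (isTRUE(cfg$structure)) {
    pca <- genotype_pca(gm_qc, n_components = min(5, nrow(gm_qc$dosage) - 1))
    write_tsv(data.frame(id = rownames(pca$scores), pca$scores),
              file.path(out, "pca.tsv"))
    stage("structure diagnostics written")
  }

  resolved <- cfg
  resolved$config_hash <- rlang::hash(cfg)
  yaml::write_yaml(resolved, file.path(out, "resolved_config.yaml"))
  stage("done: ", out)
  invisible(list(h2_table = h2_table, cv_summary = cv_summary,
                 cv_rounds = cv_round_tab, qc_report = qc_rep,
                 out_dir = out))
}

write_tsv <- function(df, path) {
  rownames(df) <- NULL
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
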
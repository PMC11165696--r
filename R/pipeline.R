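#' Pipeline configuration
#'
#' Bundles every tunable of the sex-stratified workflow with its
#' conventional default: coverage slope threshold `0.002259329`,
#' `9999` beta-diversity permutations, effect-size cutoff `0.2`,
#' pruning cutoffs GFI >= 0.90 / RMSEA <= 0.08, 10 CV folds, SMOTE
#' `k = 5` at ratio 1, 128 Dirichlet Monte-Carlo instances with prior
#' mass 0.5. A single master seed derives every stage's seed.
#'
#' @param sex stratum to analyze, `"male"` or `"female"`.
#' @param slope_max rarefaction slope threshold.
#' @param n_instances,prior Dirichlet Monte-Carlo settings.
#' @param effect_threshold taxon-selection cutoff on |effect|.
#' @param max_candidates strongest selected taxa (per direction) passed
#'   to the SEM search.
#' @param gfi_min,rmsea_max SEM pruning feasibility cutoffs.
#' @param folds,smote_k,smote_ratio risk-model settings.
#' @param n_perm permutations for PERMANOVA / PERMDISP.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sex = "female", slope_max = 0.002259329,
                            n_instances = 128L, prior = 0.5,
                            effect_threshold = 0.2,
                            max_candidates = 6L,
                            gfi_min = 0.90, rmsea_max = 0.08,
                            folds = 10L, smote_k = 5L, smote_ratio = 1.0,
                            n_perm = 9999L, seed = 1L) {
  stopifnot(sex %in% c("male", "female"),
            slope_max > 0, effect_threshold > 0, n_perm >= 1)
  structure(list(sex = sex, slope_max = slope_max,
                 n_instances = as.integer(n_instances), prior = prior,
                 effect_threshold = effect_threshold,
                 max_candidates = as.integer(max_candidates),
                 gfi_min = gfi_min, rmsea_max = rmsea_max,
                 folds = as.integer(folds), smote_k = as.integer(smote_k),
                 smote_ratio = smote_ratio, n_perm = as.integer(n_perm),
                 seed = as.integer(seed)), class = "pipeline_config")
}

#' Run the full risk-estimation workflow on one sex stratum
#'
#' Screening -> group assignment -> coverage rarefaction -> Dirichlet
#' Monte-Carlo CLR -> alpha/beta diversity report -> effect-size
#' screening -> taxon selection -> SEM pruning -> measurement submodel
#' -> blinded factor scores -> SMOTE / cross-validated logistic risk
#' model -> pooled ROC. When `out_dir` is given, every intermediate
#' artifact is persisted (TSV/JSON) and a `pipeline_complete.json`
#' marker is written last.
#'
#' If the effect-size screen selects no taxa, the pipeline stops before
#' the SEM stage and returns with `status = "no_candidate_taxa"`.
#'
#' @param counts genus count matrix (samples x genera).
#' @param roster screening-flag data.frame (see [apply_exclusions()]).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for artifacts.
#' @return a results bundle (list) with elements `audit`, `metadata`,
#'   `rarefied`, `diversity`, `effects`, `selection`, `sem`,
#'   `measurement`, `scores`, `risk`, `status`.
#' @export
run_pipeline <- function(counts, roster, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  persist <- function(name, writer) {
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      writer(file.path(out_dir, name))
    }
  }
  bundle <- list(config = config, status = "running")

  scr <- apply_exclusions(roster)
  meta <- assign_groups(scr$roster)
  bundle$audit <- scr$audit
  log_stage("screen", "%d -> %d participants; seed %d",
            scr$audit$n_input, scr$audit$n_remaining, config$seed)
  keep <- meta$sex == config$sex & meta$group %in% c("depression", "control")
  meta <- meta[keep, , drop = FALSE]
  meta$group <- droplevels(meta$group)
  if (sum(meta$group == "depression") < 2L || sum(meta$group == "control") < 2L)
    stopf("stage screen: stratum '%s' needs >= 2 cases and >= 2 controls",
          config$sex)
  counts <- counts[meta$sample_id[meta$sample_id %in% rownames(counts)], ,
                   drop = FALSE]
  meta <- meta[meta$sample_id %in% rownames(counts), , drop = FALSE]
  bundle$metadata <- meta
  persist("metadata.tsv", function(p)
    write.table(meta, p, sep = "\t", quote = FALSE, row.names = FALSE))

  rar <- coverage_rarefy(counts, slope_max = config$slope_max,
                         seed = derive_seed(config$seed, 2L))
  meta <- meta[meta$sample_id %in% rownames(rar$table), , drop = FALSE]
  bundle$rarefied <- rar
  log_stage("rarefy", "%d samples x %d genera; %d excluded",
            nrow(rar$table), ncol(rar$table), length(rar$excluded))
  persist("rarefied_counts.tsv", function(p) write_count_table(rar$table, p))

  clr_arr <- dirichlet_clr(rar$table, n_instances = config$n_instances,
                           prior = config$prior,
                           seed = derive_seed(config$seed, 3L))
  clr_med <- median_clr(clr_arr)
  log_stage("clr", "%d instances x %d samples x %d taxa",
            dim(clr_arr)[1], dim(clr_arr)[2], dim(clr_arr)[3])

  groups <- factor(meta$group, levels = c("control", "depression"))
  alpha <- alpha_diversity(rar$table)
  D <- bray_curtis(rar$table)
  pmv <- permanova(D, groups, n_perm = config$n_perm,
                   seed = derive_seed(config$seed, 4L))
  pdp <- permdisp(D, groups, n_perm = config$n_perm,
                  seed = derive_seed(config$seed, 5L))
  bundle$diversity <- list(alpha = alpha, permanova = pmv, permdisp = pdp)
  log_stage("diversity", "PERMANOVA p = %.4g, PERMDISP p = %.4g", pmv$p, pdp$p)
  persist("alpha_diversity.tsv", function(p)
    write.table(alpha, p, sep = "\t", quote = FALSE, row.names = FALSE))
  persist("beta_diversity.json", function(p)
    jsonlite::write_json(list(permanova = pmv[c("F", "p")],
                              permdisp = pdp[c("F", "p")]), p,
                         auto_unbox = TRUE, digits = NA))

  eff <- aldex_effect(clr_arr, groups, seed = derive_seed(config$seed, 6L))
  pq <- wilcoxon_bh(clr_arr, groups)
  effects <- merge(eff, pq, by = "taxon", sort = FALSE)
  sel <- classify_taxa(effects, threshold = config$effect_threshold)
  effects$class <- sel$class$class[match(effects$taxon, sel$class$taxon)]
  bundle$effects <- effects
  bundle$selection <- sel[c("more", "less")]
  log_stage("diffabund", "%d more / %d less abundant at |effect| > %g",
            length(sel$more), length(sel$less), config$effect_threshold)
  persist("effects.tsv", function(p)
    write.table(effects, p, sep = "\t", quote = FALSE, row.names = FALSE))

  if (length(sel$more) + length(sel$less) == 0L) {
    bundle$status <- "no_candidate_taxa"
    log_stage("sem", "no candidate taxa at threshold %g; stopping",
              config$effect_threshold)
    persist("pipeline_complete.json", function(p)
      jsonlite::write_json(list(status = bundle$status), p, auto_unbox = TRUE))
    return(bundle)
  }

  y <- as.integer(groups == "depression")
  # classify_taxa orders by |effect|; feed the strongest candidates to
  # the greedy SEM search (the search scales with the square of the
  # candidate count, and weak candidates are pruned first anyway)
  sel <- list(more = head(sel$more, config$max_candidates),
              less = head(sel$less, config$max_candidates))
  pruned <- prune_model(sel, clr_med, y,
                        gfi_min = config$gfi_min, rmsea_max = config$rmsea_max)
  bundle$sem <- pruned
  log_stage("sem", "pruned to %d indicators + %d direct; GFI %.3f RMSEA %.3f",
            length(unlist(pruned$spec$latents)), length(pruned$spec$direct),
            pruned$fit$gfi, pruned$fit$rmsea)
  persist("sem_fit.json", function(p) write_model(pruned$fit, p))

  meas <- measurement_submodel(pruned$fit)
  scores <- factor_scores(meas, clr_med)
  bundle$measurement <- meas
  bundle$scores <- scores
  log_stage("scores", "%d samples x %d score column(s)",
            nrow(scores), ncol(scores))

  risk <- cv_risk_model(scores, y, folds = config$folds,
                        seed = derive_seed(config$seed, 8L),
                        smote_k = config$smote_k,
                        smote_ratio = config$smote_ratio)
  bundle$risk <- risk
  log_stage("risk", "pooled CV AUC = %.3f (resubstitution %.3f)",
            risk$cv_auc, risk$resubstitution_auc)
  persist("risk_model.json", function(p)
    write_model(list(measurement = meas, risk = risk), p))
  persist("roc_curve.tsv", function(p)
    write.table(risk$roc$curve, p, sep = "\t", quote = FALSE, row.names = FALSE))

  bundle$status <- "complete"
  persist("pipeline_complete.json", function(p)
    jsonlite::write_json(list(status = "complete", seed = config$seed), p,
                         auto_unbox = TRUE))
  bundle
}
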
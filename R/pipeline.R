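#' Pipeline configuration
#'
#' Thresholds and grids for the two-round delimitation pipeline. Defaults
#' follow the analysis protocol: first-round inclusion requires strictly less
#' than 25% of the element's measurements missing (a specimen at exactly 25%
#' goes to round 2); specimens with classification uncertainty at or above
#' 0.05 are removed; a clustering is stable when its BIC exceeds every
#' different-K competitor by more than 2.
#'
#' @param missing_gate Round-1 inclusion threshold on missing fraction
#'   (strict `<`; default 0.25).
#' @param uncertainty Posterior-uncertainty exclusion threshold (inclusive;
#'   default 0.05).
#' @param stability_delta BIC stability margin (default 2).
#' @param K_range Candidate cluster numbers (default 1:6).
#' @param families Covariance families (default all six).
#' @param max_pcs Cap on stepped principal-component inclusion (default 4).
#' @param folds CV folds for rank selection (default 5).
#' @param impute_mode `"regularized"` or `"em"`.
#' @param supervised Re-cluster elements at the maximum K found across
#'   elements in the same run (default TRUE).
#' @param log_transform Re-express measurements as natural logs before
#'   scaling (variant analysis; default FALSE).
#' @param seed Run-level seed; all stage seeds derive from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(missing_gate = 0.25, uncertainty = 0.05,
                            stability_delta = 2, K_range = 1:6,
                            families = gmm_families, max_pcs = 4L,
                            folds = 5L, impute_mode = "regularized",
                            supervised = TRUE, log_transform = FALSE,
                            seed = 1L) {
  structure(list(missing_gate = missing_gate, uncertainty = uncertainty,
                 stability_delta = stability_delta, K_range = K_range,
                 families = families, max_pcs = as.integer(max_pcs),
                 folds = as.integer(folds), impute_mode = impute_mode,
                 supervised = supervised, log_transform = log_transform,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Keep only confidently classified specimens
#'
#' @param assignment A `gmm_assignment`.
#' @param threshold Exclusion threshold, inclusive (default 0.05): a specimen
#'   is kept when `uncertainty < threshold`. Filtering is idempotent.
#' @return Logical keep vector.
#' @export
filter_uncertain <- function(assignment, threshold = 0.05) {
  stopifnot(inherits(assignment, "gmm_assignment"))
  assignment$uncertainty < threshold
}

# relabel mixture components in increasing order of mean size (first column
# of the score space), so cluster 1 is always the smallest morphotype
order_components <- function(model, assignment) {
  ord <- order(model$means[, 1])
  perm <- match(seq_len(model$K), ord)  # old label -> new label
  model$means <- model$means[ord, , drop = FALSE]
  model$covariances <- model$covariances[ord]
  model$weights <- model$weights[ord]
  assignment$z <- assignment$z[, ord, drop = FALSE]
  assignment$labels <- perm[assignment$labels]
  list(model = model, assignment = assignment)
}

# scale (optionally after log), impute with CV rank choice, PCA
prepare_scores <- function(ds, config, seed) {
  M <- ds$measurements
  if (config$log_transform) M <- log(M)
  # codes must be observed at least twice with positive variance
  n_obs <- colSums(!is.na(M))
  sds <- apply(M, 2, stats::sd, na.rm = TRUE)
  keep <- n_obs >= 2 & !is.na(sds) & sds > 0
  dropped <- colnames(M)[!keep]
  M <- M[, keep, drop = FALSE]
  imp <- impute_cv(M, folds = config$folds, mode = config$impute_mode,
                   seed = seed)
  sc <- fit_scaling(imp$completed)
  Z <- scale_matrix(imp$completed, sc)
  list(imputation = imp, pca = pca_morpho(Z), dropped_codes = dropped)
}

analyse_round1 <- function(ds, config, seed) {
  mf <- missing_fraction(ds)
  included <- mf < config$missing_gate
  if (sum(included) < 5) stop("fewer than 5 specimens pass the round-1 missingness gate")
  sub <- subset_specimens(ds, included)
  prep <- prepare_scores(sub, config, seed)
  stepped <- stepped_pc_selection(prep$pca, K_range = config$K_range,
                                  families = config$families,
                                  max_pcs = config$max_pcs,
                                  stability_delta = config$stability_delta,
                                  seed = seed)
  scores <- prep$pca$scores[, seq_len(stepped$n_pcs_used), drop = FALSE]
  asn <- classify(stepped$model, scores)
  oc <- order_components(stepped$model, asn)
  keep <- filter_uncertain(oc$assignment, config$uncertainty)
  list(ids = sub$meta$specimen_id, dataset = sub, prep = prep,
       stepped = stepped, model = oc$model, assignment = oc$assignment,
       scores = scores, kept = keep,
       excluded_ids = sub$meta$specimen_id[!keep])
}

supervise_at_K <- function(r1, K, config, seed) {
  # the supervised re-run asks whether substructure hides beyond the primary
  # size axis, so it sees at least the first two components
  m <- min(max(r1$stepped$n_pcs_used, 2L), ncol(r1$prep$pca$scores))
  scores <- r1$prep$pca$scores[, seq_len(m), drop = FALSE]
  sel <- select_model(scores, K_range = K, families = config$families,
                      stability_delta = config$stability_delta, seed = seed)
  asn <- classify(sel$model, scores)
  oc <- order_components(sel$model, asn)
  keep <- filter_uncertain(oc$assignment, config$uncertainty)
  list(model = oc$model, assignment = oc$assignment, kept = keep,
       bic_table = sel$bic_table, n_pcs_used = m)
}

analyse_round2 <- function(ds, K_fixed, n_pcs, config, seed) {
  # round 2: every specimen re-enters (poor specimens, round-1 exclusions,
  # type specimens and localized specimens are all members of this superset);
  # same method as round 1, with K fixed and the round-1 dimensionality
  prep <- prepare_scores(ds, config, seed)
  m <- min(n_pcs, ncol(prep$pca$scores))
  sel <- select_model(prep$pca$scores[, seq_len(m), drop = FALSE],
                      K_range = K_fixed, families = config$families,
                      stability_delta = config$stability_delta, seed = seed)
  scores <- prep$pca$scores[, seq_len(m), drop = FALSE]
  asn <- classify(sel$model, scores)
  oc <- order_components(sel$model, asn)
  keep <- filter_uncertain(oc$assignment, config$uncertainty)
  list(ids = ds$meta$specimen_id, dataset = ds, prep = prep, model = oc$model,
       assignment = oc$assignment, kept = keep, bic_table = sel$bic_table)
}

#' Run the two-round morphotype delimitation pipeline
#'
#' Per element: (1) specimens with less than 25% missing measurements are
#' imputed (iterative PCA, CV-selected rank), scaled, reduced by PCA, and
#' clustered by stepped BIC model selection; specimens with classification
#' uncertainty >= 0.05 are removed. (2) If requested, elements whose stable K
#' is below the maximum K found across elements are re-clustered supervised
#' at that maximum. (3) A second-round dataset containing every specimen
#' (including those beyond the missingness gate, round-1 exclusions, type
#' specimens and localized specimens) is imputed and clustered at the K fixed
#' by round 1. ANOVA diagnostics and, for femora, per-cluster mass summaries
#' are computed from observed cells only.
#'
#' @param datasets Named list of [specimen_dataset()] objects (one or more
#'   elements).
#' @param config A [pipeline_config()].
#' @return Object of class `pipeline_result`: per element, the round-1 and
#'   round-2 models, assignments, kept/excluded specimens, the supervised
#'   re-run (if any), diagnostics and mass summaries; plus a `labels` data
#'   frame across rounds with disjoint round tags and a `report` list
#'   (thresholds, seeds, ranks, BIC tables) for serialization.
#' @export
run_pipeline <- function(datasets, config = pipeline_config()) {
  if (inherits(datasets, "specimen_dataset"))
    datasets <- stats::setNames(list(datasets), datasets$element)
  stopifnot(length(datasets) >= 1)
  elements <- vapply(datasets, function(d) d$element, "")
  names(datasets) <- elements

  res <- list()
  for (i in seq_along(datasets)) {
    res[[elements[i]]] <- list(
      round1 = analyse_round1(datasets[[i]], config,
                              seed = config$seed + 101L * i))
  }
  # supervised re-run at the maximum K observed across elements
  K_by_element <- vapply(res, function(r) r$round1$model$K, 0L)
  K_max <- max(K_by_element)
  for (el in elements) {
    r1 <- res[[el]]$round1
    if (config$supervised && r1$model$K < K_max) {
      res[[el]]$supervised <- supervise_at_K(
        r1, K_max, config, seed = config$seed + 503L)
    }
    final <- if (!is.null(res[[el]]$supervised)) res[[el]]$supervised else r1
    res[[el]]$final_K <- final$model$K
    res[[el]]$final_model <- final$model
    res[[el]]$final_assignment <- final$assignment
    res[[el]]$final_kept <- final$kept
  }
  # round 2 at fixed K, on the round-1 dimensionality
  for (i in seq_along(datasets)) {
    el <- elements[i]
    n_pcs <- if (!is.null(res[[el]]$supervised))
      res[[el]]$supervised$n_pcs_used else res[[el]]$round1$stepped$n_pcs_used
    res[[el]]$round2 <- analyse_round2(datasets[[i]], res[[el]]$final_K, n_pcs,
                                       config, seed = config$seed + 211L * i)
  }
  # diagnostics on observed cells of confidently classified round-1 specimens
  for (i in seq_along(datasets)) {
    el <- elements[i]
    r1 <- res[[el]]$round1
    kept <- res[[el]]$final_kept
    labs <- res[[el]]$final_assignment$labels[kept]
    obsM <- r1$dataset$measurements[kept, , drop = FALSE]
    res[[el]]$anova <- anova_diagnostics(obsM, labs)
    if (el == "femur" && "F3" %in% colnames(obsM))
      res[[el]]$mass <- suppressWarnings(
        summarize_cluster_masses(obsM[, "F3"], labs))
  }
  out <- structure(list(elements = res, config = config,
                        labels = pipeline_labels(res)),
                   class = "pipeline_result")
  out
}

pipeline_labels <- function(res) {
  rows <- list()
  for (el in names(res)) {
    r <- res[[el]]
    rows[[length(rows) + 1]] <- data.frame(
      element = el, specimen_id = r$round1$ids, round = "first",
      cluster = r$final_assignment$labels,
      uncertainty = r$final_assignment$uncertainty,
      status = ifelse(r$final_kept, "included", "excluded_uncertainty"),
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      element = el, specimen_id = r$round2$ids, round = "second",
      cluster = r$round2$assignment$labels,
      uncertainty = r$round2$assignment$uncertainty,
      status = ifelse(r$round2$kept, "included", "excluded_uncertainty"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' @export
print.pipeline_result <- function(x, ...) {
  for (el in names(x$elements)) {
    r <- x$elements[[el]]
    cat(sprintf("%s: round-1 n = %d, K = %d (%s, %d PCs, stable = %s)%s; round-2 n = %d; excluded by uncertainty: %d\n",
                el, length(r$round1$ids), r$round1$model$K,
                r$round1$model$family, r$round1$stepped$n_pcs_used,
                r$round1$stepped$stable,
                if (!is.null(r$supervised))
                  sprintf("; supervised K = %d", r$final_K) else "",
                length(r$round2$ids), length(r$round1$excluded_ids)))
  }
  invisible(x)
}

#' Resolve taxonomy from a pipeline result
#'
#' Collects type-specimen metadata (`type_taxon`, `type_year`, `type_month`
#' columns) across elements, attaches each type's cluster label and
#' uncertainty (round-1 final labels when the specimen passed the missingness
#' gate, round-2 labels otherwise) and runs [resolve_taxa()].
#'
#' @param result A `pipeline_result`.
#' @param referred Optional literature placements (see [resolve_taxa()]).
#' @return A `taxon_resolution`, or `NULL` when no type metadata exists.
#' @export
pipeline_taxonomy <- function(result, referred = NULL) {
  rows <- list()
  for (el in names(result$elements)) {
    r <- result$elements[[el]]
    m1 <- r$round1$dataset$meta
    if (!is.null(m1$type_taxon)) {
      sel <- !is.na(m1$type_taxon)
      if (any(sel))
        rows[[length(rows) + 1]] <- data.frame(
          taxon_name = m1$type_taxon[sel], pub_year = m1$type_year[sel],
          pub_month = if (!is.null(m1$type_month)) m1$type_month[sel] else NA,
          cluster = r$final_assignment$labels[sel],
          uncertainty = r$final_assignment$uncertainty[sel],
          specimen_id = m1$specimen_id[sel], stringsAsFactors = FALSE)
    }
    # types that only entered in round 2 (beyond the missingness gate)
    m2 <- r$round2$dataset$meta
    if (!is.null(m2$type_taxon)) {
      sel <- !is.na(m2$type_taxon) & !(m2$specimen_id %in% m1$specimen_id)
      if (any(sel))
        rows[[length(rows) + 1]] <- data.frame(
          taxon_name = m2$type_taxon[sel], pub_year = m2$type_year[sel],
          pub_month = if (!is.null(m2$type_month)) m2$type_month[sel] else NA,
          cluster = r$round2$assignment$labels[sel],
          uncertainty = r$round2$assignment$uncertainty[sel],
          specimen_id = m2$specimen_id[sel], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows) && is.null(referred)) return(NULL)
  types <- if (length(rows)) do.call(rbind, rows)
           else data.frame(taxon_name = character(), pub_year = integer(),
                           pub_month = integer(), cluster = integer(),
                           uncertainty = numeric(), specimen_id = character())
  resolve_taxa(types, referred = referred,
               uncertainty_threshold = result$config$uncertainty)
}

#' Write pipeline outputs to disk
#'
#' Writes three files: `labels.csv` (per specimen and round: cluster,
#' uncertainty, inclusion status), `cluster_ranges.csv` (per element, cluster
#' and code: min/max/n over observed cells of confidently classified round-1
#' specimens) and `run_report.json` (thresholds, seeds, selected ranks and
#' models, BIC tables, exclusion counts).
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory ", dir)
  f_labels <- file.path(dir, "labels.csv")
  utils::write.csv(result$labels, f_labels, row.names = FALSE, na = "")

  ranges <- list()
  for (el in names(result$elements)) {
    r <- result$elements[[el]]
    kept <- r$final_kept
    labs <- r$final_assignment$labels[kept]
    M <- r$round1$dataset$measurements[kept, , drop = FALSE]
    for (k in sort(unique(labs))) for (code in colnames(M)) {
      v <- M[labs == k, code]
      v <- v[!is.na(v)]
      if (!length(v)) next
      ranges[[length(ranges) + 1]] <- data.frame(
        element = el, cluster = k, code = code,
        min_mm = min(v), max_mm = max(v), n = length(v))
    }
  }
  f_ranges <- file.path(dir, "cluster_ranges.csv")
  utils::write.csv(do.call(rbind, ranges), f_ranges, row.names = FALSE)

  report <- list(
    config = unclass(result$config),
    elements = lapply(result$elements, function(r) list(
      round1 = list(
        n = length(r$round1$ids), K = r$round1$model$K,
        family = r$round1$model$family,
        n_pcs_used = r$round1$stepped$n_pcs_used,
        stable = r$round1$stepped$stable,
        delta_bic = r$round1$stepped$delta_bic,
        ncp = r$round1$prep$imputation$ncp,
        cv_errors = as.list(r$round1$prep$imputation$cv_errors),
        imputed_fraction = mean(r$round1$prep$imputation$imputed_mask),
        dropped_codes = r$round1$prep$dropped_codes,
        excluded_uncertainty = r$round1$excluded_ids,
        bic_table = r$round1$stepped$bic_table),
      supervised_K = if (!is.null(r$supervised)) r$final_K else NULL,
      round2 = list(
        n = length(r$round2$ids), K = r$round2$model$K,
        family = r$round2$model$family,
        ncp = r$round2$prep$imputation$ncp,
        imputed_fraction = mean(r$round2$prep$imputation$imputed_mask),
        excluded_uncertainty = r$round2$ids[!r$round2$kept]))))
  f_report <- file.path(dir, "run_report.json")
  jsonlite::write_json(report, f_report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(c(f_labels, f_ranges, f_report))
}
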
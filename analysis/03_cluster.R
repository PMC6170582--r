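#!/usr/bin/env Rscript
# Run the full two-round delimitation pipeline on the simulated study:
# round 1 on specimens under the 25% missingness gate (impute -> PCA ->
# stepped BIC model selection -> 0.05 uncertainty filter), a supervised
# re-fit of lower-K elements at the cross-element maximum K, and a round-2
# re-analysis of all specimens at the fixed K. Scores labels against truth.

library(aepymorph)

stopifnot(file.exists("results/synthetic/tarsometatarsus.csv"))
tmt <- read_specimen_table("results/synthetic/tarsometatarsus.csv", "tarsometatarsus")
fem <- read_specimen_table("results/synthetic/femur.csv", "femur")

res <- run_pipeline(list(fem, tmt), pipeline_config(seed = 1L))
print(res)
files <- write_results(res, "results/pipeline")

truth <- list(
  tarsometatarsus = utils::read.csv("results/synthetic/tarsometatarsus_truth.csv"),
  femur = utils::read.csv("results/synthetic/femur_truth.csv"))
for (el in names(res$elements)) {
  r <- res$elements[[el]]
  tt <- truth[[el]]
  tv <- if (el == "femur") tt$true_primary else tt$true_cluster
  kept <- r$final_kept
  tv1 <- tv[match(r$round1$ids, tt$specimen_id)]
  ari <- if (requireNamespace("mclust", quietly = TRUE))
    round(mclust::adjustedRandIndex(r$final_assignment$labels[kept], tv1[kept]), 3)
  else NA
  message(sprintf(
    "%s: unsupervised K = %d on %d PCs (stable = %s); final K = %d; %d of %d confidently classified; ARI vs truth %s",
    el, r$round1$model$K, r$round1$stepped$n_pcs_used, r$round1$stepped$stable,
    r$final_K, sum(kept), length(kept), ari))
}
message("Wrote ", paste(basename(files), collapse = ", "), " under results/pipeline/.")
if (!is.null(res$elements$femur$supervised)) {
  message("The femoral supervised re-fit at the tarsometatarsal K separated ",
          "the planted species-level subgroups of the middle morphotype.")
} else {
  message("The femoral data resolved the planted subgroups without a ",
          "supervised re-fit on this draw (round-1 K already matched the ",
          "tarsometatarsal K).")
}
message("Round 2 re-clusters every specimen (including broken ones beyond ",
        "the missingness gate) at the round-1 K; labels for both rounds are ",
        "tagged apart in labels.csv.")
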
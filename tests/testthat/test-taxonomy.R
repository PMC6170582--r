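# The four published cluster -> name resolutions, as (name, year, month) data.
published_type_matrix <- function() {
  data.frame(
    taxon_name = c("modestus", "hildebrandti", "agilis", "rudis",
                   "hildebrandti", "gracilis", "lentus",
                   "medius", "cursor",
                   "titan", "ingens"),
    pub_year  = c(1869, 1893, 1894, 1894,
                  1893, 1913, 1894,
                  1869, 1894,
                  1894, 1894),
    pub_month = c(NA, NA, NA, NA,
                  NA, NA, NA,
                  NA, NA,
                  1, 2),
    cluster   = c("1", "1", "1", "1",
                  "2a", "2a", "2a",
                  "2b", "2b",
                  "3", "3"),
    uncertainty = c(0, 0.2, 0, 0,   # the femoral hildebrandti type is poorly
                    0, 0, 0,        # predicted; its tarsometatarsus carries it
                    0, 0,
                    0, 0),
    stringsAsFactors = FALSE)
}

test_that("seniority resolution reproduces the published taxonomic matrix", {
  types <- published_type_matrix()
  # maximus (1851) is referable to cluster 2b from published measurements
  referred <- data.frame(taxon_name = "maximus", pub_year = 1851,
                         pub_month = NA, cluster = "2b")
  res <- resolve_taxa(types, referred = referred)
  out <- stats::setNames(res$senior_name, res$cluster)
  expect_identical(unname(out["1"]), "modestus")     # 1869
  expect_identical(unname(out["2a"]), "hildebrandti") # 1893
  expect_identical(unname(out["2b"]), "maximus")     # 1851 beats medius 1869
  expect_identical(unname(out["3"]), "titan")        # Jan 1894 beats Feb 1894
  expect_equal(res$pub_year[res$cluster == "3"], 1894)
  expect_equal(res$pub_month[res$cluster == "3"], 1)
})

test_that("seniority is permutation invariant, deterministic, and skips poorly predicted types", {
  types <- published_type_matrix()
  for (s in 1:5) {
    perm <- withr::with_seed(s, sample(nrow(types)))
    res <- resolve_taxa(types[perm, ])
    expect_identical(res$senior_name[res$cluster == "3"], "titan")
    # without the referred maximus, 2b resolves to its oldest clustered type
    expect_identical(res$senior_name[res$cluster == "2b"], "medius")
  }
  # a poorly predicted type cannot carry the name: hildebrandti's femur
  # (uncertainty 0.2) does not name cluster 1
  res <- resolve_taxa(published_type_matrix())
  expect_identical(res$senior_name[res$cluster == "1"], "modestus")
  ev <- attr(res, "evidence")
  expect_false(ev$well_predicted[ev$taxon_name == "hildebrandti" & ev$cluster == "1"])
})

test_that("clusters without type evidence come back unnamed", {
  types <- data.frame(taxon_name = "x", pub_year = 1900, cluster = "1")
  res <- resolve_taxa(types, clusters = c("1", "2"))
  expect_identical(res$senior_name[res$cluster == "2"], "unnamed")
})

test_that("interval assignment reproduces the published literature placements", {
  tmt5 <- published_diagnostic_intervals("Tmt5")
  expect_true(tmt5$discrete)
  expect_identical(interval_assign(127, tmt5), "2b")   # the maximus type series
  expect_identical(interval_assign(90, tmt5), "unassigned")  # gap
  tmt9 <- published_diagnostic_intervals("Tmt9")
  expect_identical(interval_assign(70, tmt9), "1")     # the betsilei type
  f3 <- published_diagnostic_intervals("F3")
  expect_false(f3$pairwise_disjoint)  # 2b and 3 touch at 253-254
  expect_identical(interval_assign(c(125, 145), f3), "1")  # the grandis range
})

test_that("interval assignment refuses non-discrete codes and flags ambiguity", {
  iv <- diagnostic_intervals("Tmt1", list(a = c(0, 10), b = c(5, 15)))
  expect_false(iv$discrete)
  expect_error(interval_assign(7, iv), "not flagged discrete")
  f3 <- published_diagnostic_intervals("F3")
  expect_identical(interval_assign(253.5, f3), "ambiguous")
  expect_identical(interval_assign(c(100, 300), f3), "ambiguous")
})

test_that("one-way ANOVA diagnostics match a hand-computed fixture", {
  M <- cbind(F1 = c(1, 2, 3, 11, 12, 13), F2 = rep(4, 6))
  labels <- c(1, 1, 1, 2, 2, 2)
  out <- anova_diagnostics(M, labels)
  r <- out[out$code == "F1", ]
  # grand mean 7: SSB = 150, SSW = 4 on (1, 4) df -> F = 150
  expect_equal(r$F, 150, tolerance = 1e-12)
  expect_equal(r$p, stats::pf(150, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(r$p, 2.554e-4, tolerance = 1e-3)
  # a constant column has zero variance everywhere: F = 0 is not significant
  r2 <- out[out$code == "F2", ]
  expect_true(r2$skipped || (!is.na(r2$F) && r2$F == 0) || is.nan(r2$F))
  expect_equal(attr(out, "alpha_bonferroni"), 0.05 / attr(out, "n_tested"))
})

test_that("identical groups give F = 0", {
  M <- cbind(F1 = c(5, 6, 7, 5, 6, 7))
  out <- anova_diagnostics(M, c(1, 1, 1, 2, 2, 2))
  expect_equal(out$F[1], 0, tolerance = 1e-12)
  expect_false(out$significant[1])
})

test_that("codes without enough per-cluster data are skipped with a reason", {
  M <- cbind(F1 = c(1, NA, NA, 10, 11, 12), F2 = c(1, 2, 3, 10, 11, 12))
  out <- anova_diagnostics(M, c(1, 1, 1, 2, 2, 2))
  expect_true(out$skipped[out$code == "F1"])
  expect_false(out$skipped[out$code == "F2"])
  expect_equal(attr(out, "n_tested"), 1)
})
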
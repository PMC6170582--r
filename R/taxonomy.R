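#' Resolve morphometric clusters to senior available names
#'
#' A cluster is named by the senior available species name among its
#' well-predicted type-specimen members: earliest publication year, ties
#' broken by publication month (an unknown month sorts after every known
#' month of that year), then alphabetically for determinism. Type specimens
#' whose classification uncertainty reaches `uncertainty_threshold` are kept
#' in the evidence chain but flagged poorly predicted and excluded from
#' seniority. Additional literature types placed by diagnostic-interval
#' assignment (rather than clustering) can be supplied via `referred` and
#' compete for seniority on equal terms. Clusters with no usable type
#' evidence are `"unnamed"`.
#'
#' @param types Data frame of type-specimen memberships with columns
#'   `taxon_name`, `pub_year`, `pub_month` (NA allowed), `cluster`,
#'   `uncertainty` (optional, defaults 0), `role` (optional), `specimen_id`
#'   (optional).
#' @param referred Optional data frame of literature placements with columns
#'   `taxon_name`, `pub_year`, `pub_month`, `cluster` (treated as
#'   well-predicted).
#' @param clusters Clusters to resolve (default: all present in the inputs).
#' @param uncertainty_threshold Exclusion threshold, inclusive (default 0.05).
#' @return Object of class `taxon_resolution`: data frame with one row per
#'   cluster (`cluster`, `senior_name`, `pub_year`, `pub_month`) and an
#'   `evidence` attribute listing every type considered with its
#'   `well_predicted` flag.
#' @export
resolve_taxa <- function(types, referred = NULL, clusters = NULL,
                         uncertainty_threshold = 0.05) {
  need <- c("taxon_name", "pub_year", "cluster")
  if (!all(need %in% names(types)))
    stop("types needs columns: ", paste(need, collapse = ", "))
  types <- as.data.frame(types)
  if (is.null(types$pub_month)) types$pub_month <- NA_integer_
  if (is.null(types$uncertainty)) types$uncertainty <- 0
  types$well_predicted <- types$uncertainty < uncertainty_threshold
  types$source <- "clustered"
  if (!is.null(referred) && nrow(referred)) {
    referred <- as.data.frame(referred)
    if (is.null(referred$pub_month)) referred$pub_month <- NA_integer_
    referred$uncertainty <- 0
    referred$well_predicted <- TRUE
    referred$source <- "referred"
    common <- c("taxon_name", "pub_year", "pub_month", "cluster",
                "uncertainty", "well_predicted", "source")
    types <- rbind(types[common], referred[common])
  }
  if (is.null(clusters)) clusters <- sort(unique(types$cluster))
  rows <- lapply(clusters, function(cl) {
    ev <- types[types$cluster == cl & types$well_predicted, , drop = FALSE]
    if (!nrow(ev))
      return(data.frame(cluster = cl, senior_name = "unnamed",
                        pub_year = NA_integer_, pub_month = NA_integer_,
                        stringsAsFactors = FALSE))
    month_key <- ifelse(is.na(ev$pub_month), 13L, ev$pub_month)
    ord <- order(ev$pub_year, month_key, ev$taxon_name)
    top <- ev[ord[1], ]
    data.frame(cluster = cl, senior_name = top$taxon_name,
               pub_year = top$pub_year, pub_month = top$pub_month,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "evidence") <- types
  class(out) <- c("taxon_resolution", "data.frame")
  out
}

#' Diagnostic measurement intervals for clusters
#'
#' Per-cluster closed intervals `[min, max]` (mm) of one measurement code,
#' used to place literature specimens that cannot enter the clustering. By
#' default the `discrete` flag is computed as pairwise non-overlap of the
#' intervals; it can be set explicitly when a published interval set is
#' diagnostic over the relevant part of its range despite a marginal overlap
#' elsewhere (the femoral least-shaft-circumference intervals overlap between
#' the two largest clusters yet separate the smallest cleanly).
#'
#' @param code Measurement code the intervals describe.
#' @param intervals Named list of `c(min, max)` per cluster.
#' @param discrete Logical or `NULL` (compute from pairwise overlap).
#' @return Object of class `diagnostic_intervals`.
#' @export
diagnostic_intervals <- function(code, intervals, discrete = NULL) {
  stopifnot(is.list(intervals), length(names(intervals)) == length(intervals))
  iv <- lapply(intervals, function(v) {
    v <- as.numeric(v)
    if (length(v) != 2 || v[1] > v[2]) stop("each interval must be c(min, max)")
    v
  })
  ord <- order(vapply(iv, `[`, 0, 1))
  iv <- iv[ord]
  overlap <- FALSE
  if (length(iv) > 1) {
    lo <- vapply(iv, `[`, 0, 1); hi <- vapply(iv, `[`, 0, 2)
    overlap <- any(lo[-1] <= hi[-length(hi)])
  }
  if (is.null(discrete)) discrete <- !overlap
  structure(list(code = code, intervals = iv, discrete = discrete,
                 pairwise_disjoint = !overlap),
            class = "diagnostic_intervals")
}

#' Assign a literature measurement to a cluster by diagnostic intervals
#'
#' A single value (or a published min--max range) is assigned to the one
#' cluster whose interval it intersects; values falling in the gaps between
#' intervals are `"unassigned"`, and queries intersecting more than one
#' interval are `"ambiguous"`. Assignment is refused (an error) for codes not
#' flagged discrete.
#'
#' @param value Numeric scalar, or length-2 vector `c(min, max)` for a range.
#' @param intervals A [diagnostic_intervals()] object.
#' @return Character scalar: a cluster name, `"unassigned"` or `"ambiguous"`.
#' @export
interval_assign <- function(value, intervals) {
  stopifnot(inherits(intervals, "diagnostic_intervals"))
  if (!intervals$discrete)
    stop(sprintf("code %s is not flagged discrete; interval assignment refused",
                 intervals$code))
  value <- as.numeric(value)
  if (length(value) == 1) value <- c(value, value)
  if (length(value) != 2 || value[1] > value[2])
    stop("value must be a scalar or c(min, max)")
  hits <- names(intervals$intervals)[vapply(intervals$intervals, function(iv)
    value[1] <= iv[2] && value[2] >= iv[1], NA)]
  if (length(hits) == 0) return("unassigned")
  if (length(hits) > 1) return("ambiguous")
  hits
}

#' Published diagnostic intervals for aepyornithid clusters
#'
#' The three interval sets used to place literature type specimens: extreme
#' trochlear breadth of the tarsometatarsus (`Tmt5`), proximal width of the
#' tarsometatarsus (`Tmt9`) and femoral least-shaft circumference (`F3`).
#' Cluster keys are `"1"`, `"2a"`, `"2b"`, `"3"`. The `F3` set is flagged
#' discrete explicitly: its two largest intervals touch (253--254 mm) but the
#' set is diagnostic over the small-bodied range where it is used.
#'
#' @param code One of `"Tmt5"`, `"Tmt9"`, `"F3"`.
#' @return A [diagnostic_intervals()] object.
#' @export
published_diagnostic_intervals <- function(code = c("Tmt5", "Tmt9", "F3")) {
  code <- match.arg(code)
  switch(code,
    Tmt5 = diagnostic_intervals("Tmt5", list(
      `1` = c(65, 79.24), `2a` = c(105, 118),
      `2b` = c(125.18, 140.2), `3` = c(164, 178))),
    Tmt9 = diagnostic_intervals("Tmt9", list(
      `1` = c(65.8, 81.46), `2a` = c(99.7, 123.1),
      `2b` = c(140.3, 150.5), `3` = c(173, 184))),
    F3 = diagnostic_intervals("F3", list(
      `1` = c(114, 158), `2a` = c(172, 210),
      `2b` = c(208, 254), `3` = c(253, 288)), discrete = TRUE))
}

#' Per-measurement ANOVA diagnostics across clusters
#'
#' One-way ANOVA of each measurement code across cluster labels, on observed
#' values only (imputed cells are excluded by passing the original matrix).
#' Significance is judged after Bonferroni correction with denominator equal
#' to the number of codes actually tested.
#'
#' @param M Numeric matrix, specimens x codes, `NA` for cells that were not
#'   observed.
#' @param labels Cluster label per specimen.
#' @param alpha Family-wise error rate before correction (default 0.05).
#' @return Data frame: `code`, `F`, `p`, `df_between`, `df_within`,
#'   `significant` (after Bonferroni), `skipped`, `reason`; the corrected
#'   alpha is in attribute `alpha_bonferroni`.
#' @export
anova_diagnostics <- function(M, labels, alpha = 0.05) {
  M <- as.matrix(M)
  stopifnot(nrow(M) == length(labels))
  rows <- lapply(colnames(M), function(code) {
    v <- M[, code]
    keep <- !is.na(v)
    g <- factor(labels[keep])
    usable <- table(g)
    if (sum(usable >= 2) < 2)
      return(data.frame(code = code, F = NA_real_, p = NA_real_,
                        df_between = NA_integer_, df_within = NA_integer_,
                        significant = NA, skipped = TRUE,
                        reason = "fewer than 2 clusters with >= 2 observations"))
    fit <- tryCatch(stats::oneway.test(v[keep] ~ g, var.equal = TRUE),
                    error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(code = code, F = NA_real_, p = NA_real_,
                        df_between = NA_integer_, df_within = NA_integer_,
                        significant = NA, skipped = TRUE,
                        reason = "degenerate data (constant within groups)"))
    data.frame(code = code, F = unname(fit$statistic), p = unname(fit$p.value),
               df_between = unname(fit$parameter[1]),
               df_within = unname(fit$parameter[2]),
               significant = NA, skipped = FALSE, reason = "")
  })
  out <- do.call(rbind, rows)
  m <- sum(!out$skipped)
  alpha_b <- alpha / max(m, 1)
  out$significant <- ifelse(out$skipped, NA, out$p < alpha_b)
  attr(out, "alpha_bonferroni") <- alpha_b
  attr(out, "n_tested") <- m
  out
}
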
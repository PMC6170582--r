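#' Body mass from femoral least-shaft circumference
#'
#' The Campbell--Marcus allometric regression for birds,
#' `log10(M) = 2.411 * log10(LCF) - 0.065`, with `M` the body mass in grams
#' and `LCF` the least-shaft circumference of the femur in mm (measurement
#' code `F3`, the circumference at minimum midshaft width). Mass is strictly
#' increasing in circumference; doubling the circumference multiplies mass by
#' `2^2.411` (about 5.32).
#'
#' @param lcf_mm Positive numeric vector of least-shaft circumferences (mm).
#' @return Data frame with `circumference_mm`, `mass_g` and `mass_kg`
#'   (unrounded; round only for presentation).
#' @examples
#' mass_from_circumference(c(114, 288))
#' @export
mass_from_circumference <- function(lcf_mm) {
  if (any(!is.finite(lcf_mm) | lcf_mm <= 0))
    stop("circumference must be strictly positive")
  mass_g <- 10^(2.411 * log10(lcf_mm) - 0.065)
  data.frame(circumference_mm = lcf_mm, mass_g = mass_g,
             mass_kg = mass_g / 1000)
}

#' Per-cluster body-mass summaries
#'
#' Mass statistics per cluster from observed (never imputed) least-shaft
#' circumferences. Statistics are computed on unrounded per-specimen masses;
#' `min`/`max`/`mean`/`sd` are reported in kg. Single-specimen clusters
#' report `sd = 0` by convention (flagged by `n = 1`); clusters without any
#' observed circumference are omitted with a warning.
#'
#' @param lcf_mm Numeric vector of observed circumferences (mm); may contain
#'   `NA` for specimens whose circumference was not observed.
#' @param labels Cluster label per specimen (same length).
#' @return Data frame, one row per cluster: `cluster`, `n`, `min_kg`,
#'   `max_kg`, `mean_kg`, `sd_kg`.
#' @export
summarize_cluster_masses <- function(lcf_mm, labels) {
  stopifnot(length(lcf_mm) == length(labels))
  keep <- !is.na(lcf_mm)
  cl <- sort(unique(labels))
  empty <- setdiff(cl, unique(labels[keep]))
  if (length(empty))
    warning("cluster(s) without observed circumference omitted: ",
            paste(empty, collapse = ", "))
  cl <- setdiff(cl, empty)
  rows <- lapply(cl, function(k) {
    m <- mass_from_circumference(lcf_mm[keep & labels == k])$mass_kg
    data.frame(cluster = k, n = length(m), min_kg = min(m), max_kg = max(m),
               mean_kg = mean(m),
               sd_kg = if (length(m) > 1) stats::sd(m) else 0)
  })
  do.call(rbind, rows)
}
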
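#' Measurement schemes for aepyornithid leg bones
#'
#' The three avian hind-limb long bones are measured with fixed series of
#' linear measurements: 20 femoral codes (`F1`--`F20`), 21 tibiotarsal codes
#' (`Tt1`--`Tt21`) and 44 tarsometatarsal codes (`Tmt1`--`Tmt44`). Each code
#' maps to an anatomical definition; two codes (`F15`, `Tt21`) appear in
#' published per-taxon measurement tables but carry no published anatomical
#' definition and are registered with description `"definition unknown"`.
#'
#' @param element One of `"femur"`, `"tibiotarsus"`, `"tarsometatarsus"`.
#' @return An object of class `measurement_scheme`: a list with `element`,
#'   `codes` (ordered character vector) and `descriptions` (named character
#'   vector, one entry per code).
#' @examples
#' sc <- measurement_scheme("femur")
#' length(sc$codes)  # 20
#' sc$descriptions[["F3"]]
#' @export
measurement_scheme <- function(element) {
  element <- match_element(element)
  codes <- scheme_codes(element)
  out <- list(element = element, codes = codes,
              descriptions = .scheme_descriptions[[element]][codes])
  class(out) <- "measurement_scheme"
  out
}

#' Ordered measurement codes for an element
#'
#' @inheritParams measurement_scheme
#' @return Character vector of measurement codes in scheme order.
#' @export
scheme_codes <- function(element) {
  element <- match_element(element)
  switch(element,
    femur            = paste0("F",   1:20),
    tibiotarsus      = paste0("Tt",  1:21),
    tarsometatarsus  = paste0("Tmt", 1:44))
}

match_element <- function(element) {
  match.arg(element, c("femur", "tibiotarsus", "tarsometatarsus"))
}

#' @export
print.measurement_scheme <- function(x, ...) {
  cat(sprintf("Measurement scheme: %s (%d codes: %s .. %s)\n",
              x$element, length(x$codes), x$codes[1], x$codes[length(x$codes)]))
  invisible(x)
}

# Anatomical definitions of the measurement codes. F15 and Tt21 occur in the
# published per-taxon tables but have no published definition.
.scheme_descriptions <- local({
  fem <- c(
    F1  = "total length",
    F2  = "minimum midshaft width",
    F3  = "circumference at minimum midshaft width",
    F4  = "maximum midshaft width",
    F5  = "circumference of caput femoris",
    F6  = "dorsoventral diameter of caput femoris",
    F7  = "proximo-distal diameter of caput femoris",
    F8  = "dorsoventral thickness of trochanter femoris",
    F9  = "maximum width of distal condyles",
    F10 = "maximum height of condylus medialis",
    F11 = "maximum height of condylus lateralis",
    F12 = "sulcus patellaris to trochanter femoris",
    F13 = "trochanter femoris to condylus medialis",
    F14 = "proximo-medial extreme of caput femoris to condylus lateralis",
    F15 = "definition unknown",
    F16 = "medio-lateral length of caput femoris",
    F17 = "dorsal extremity of crista trochanteris to dorsal extremity of caput femoris",
    F18 = "ventral extremity of crista trochanteris to ventral extremity of caput femoris",
    F19 = "trochlea fibularis width",
    F20 = "distance between medial and condylus lateralis")
  tib <- c(
    Tt1  = "total length",
    Tt2  = "minimum midshaft width",
    Tt3  = "circumference at Tt2",
    Tt4  = "maximum midshaft width",
    Tt5  = "width of condyles",
    Tt6  = "maximum height, condylus medialis",
    Tt7  = "maximum height, condylus lateralis",
    Tt8  = "maximum width of head, including crest",
    Tt9  = "width of proximal end, including crista cnemialis cranialis",
    Tt10 = "width of head",
    Tt11 = "distance between cnemial crests",
    Tt12 = "extreme width of posterior groove",
    Tt13 = "posterior groove to external condyle",
    Tt14 = "posterior groove height to external condyle",
    Tt15 = "external condyle width",
    Tt16 = "external condyle height",
    Tt17 = "outer cnemial crest width",
    Tt18 = "outer crista cnemialis lateralis height",
    Tt19 = "total outer crista cnemialis lateralis ridge length",
    Tt20 = "tibia scar",
    Tt21 = "definition unknown")
  tmt <- c(
    Tmt1  = "length",
    Tmt2  = "minimum shaft thickness (not midshaft)",
    Tmt3  = "shaft width at Tmt2",
    Tmt4  = "trochlea III width",
    Tmt5  = "width (all trochleae)",
    Tmt6  = "head height at midpoint, including ridge",
    Tmt7  = "maximum height, proximal end of metatarsal II",
    Tmt8  = "maximum height, proximal end of metatarsal IV",
    Tmt9  = "head width",
    Tmt10 = "inside curve (plantar) across three trochleae",
    Tmt11 = "outside curve (cranial) across three trochleae",
    Tmt12 = "trochlea III, plantar width",
    Tmt13 = "trochlea III, cranial width",
    Tmt14 = "trochlea II, medial thickness",
    Tmt15 = "trochlea II, central thickness",
    Tmt16 = "trochlea II, lateral thickness",
    Tmt17 = "trochlea III, medial thickness",
    Tmt18 = "trochlea III, central thickness",
    Tmt19 = "trochlea III, lateral thickness",
    Tmt20 = "trochlea IV, medial thickness",
    Tmt21 = "trochlea IV, central thickness",
    Tmt22 = "trochlea IV, lateral thickness",
    Tmt23 = "trochlea III, diagonal length",
    Tmt24 = "trochlea IV, diagonal length",
    Tmt25 = "trochlea III, medial length, outside to notch",
    Tmt26 = "trochlea III, medial length, outside with notch",
    Tmt27 = "trochlea III, medio-cranial length",
    Tmt28 = "trochlea III, lateral-cranial length",
    Tmt29 = "trochlea III, lateral length, outside",
    Tmt30 = "trochlea II length",
    Tmt31 = "trochlea IV length",
    Tmt32 = "trochlea III, cranial (peak to peak) notch width",
    Tmt33 = "total width at foramina",
    Tmt34 = "foramina width",
    Tmt35 = "maximum anterior-posterior depth of external cotyle",
    Tmt36 = "minimum depth of head",
    Tmt37 = "maximum depth at hypotarsal ridge (no ridge)",
    Tmt38 = "maximum depth at hypotarsal ridge (inclusive of ridge)",
    Tmt39 = "proximal-lateral extreme of head to hypotarsal ridge extreme",
    Tmt40 = "proximal-medial extreme of head to hypotarsal ridge extreme",
    Tmt41 = "length, trochlea II to head",
    Tmt42 = "length, trochlea IV to head",
    Tmt43 = "diagonal length, trochlea II to head",
    Tmt44 = "diagonal length, trochlea IV to head")
  list(femur = fem, tibiotarsus = tib, tarsometatarsus = tmt)
})

# Anatomically structured missingness blocks: a break at one end of a bone
# removes the measurements of that end together, and any measurement spanning
# the whole bone (total and end-to-end lengths) with it.
#' Breakage blocks for an element
#'
#' Groups an element's measurement codes into anatomical regions that go
#' missing together when a bone is broken: `proximal`, `distal`, `shaft`, and
#' `lengths` (whole-bone spans, lost whenever any region is lost).
#'
#' @inheritParams measurement_scheme
#' @return Named list of character vectors partitioning the scheme's codes.
#' @export
breakage_blocks <- function(element) {
  element <- match_element(element)
  switch(element,
    femur = list(
      lengths  = c("F1", "F12", "F13", "F14", "F15"),
      proximal = c("F5", "F6", "F7", "F8", "F16", "F17", "F18"),
      distal   = c("F9", "F10", "F11", "F19", "F20"),
      shaft    = c("F2", "F3", "F4")),
    tibiotarsus = list(
      lengths  = c("Tt1", "Tt21"),
      proximal = c("Tt8", "Tt9", "Tt10", "Tt11", "Tt12", "Tt17", "Tt18", "Tt19"),
      distal   = c("Tt5", "Tt6", "Tt7", "Tt13", "Tt14", "Tt15", "Tt16", "Tt20"),
      shaft    = c("Tt2", "Tt3", "Tt4")),
    tarsometatarsus = list(
      lengths  = c("Tmt1", "Tmt41", "Tmt42", "Tmt43", "Tmt44"),
      proximal = c("Tmt6", "Tmt7", "Tmt8", "Tmt9",
                   paste0("Tmt", 33:40)),
      distal   = c("Tmt4", "Tmt5", paste0("Tmt", 10:32)),
      shaft    = c("Tmt2", "Tmt3")))
}
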
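#' Carbon counts of the supported metabolites
#'
#' Backbone carbon numbering is 1-based biochemical numbering (C1 = carboxyl
#' carbon).
#'
#' @return Named integer vector of metabolite carbon counts.
#' @export
metabolite_carbons <- function() {
  c(Alanine = 3L, Glycine = 2L, Serine = 3L, Malate = 4L,
    Glutamate = 5L, Proline = 5L)
}

#' Construct a TMS-derivative fragment definition
#'
#' A fragment definition ties a GC-EI-MS mass fragment of a TMS derivative to
#' the subset of metabolite backbone carbons it retains. The `formula` and
#' `m0_mz` actually used in computations must be self-consistent
#' (`nominal_mass(formula) == m0_mz`); where a published registry row is not,
#' the verbatim values are kept in `formula_verbatim`/`m0_verbatim` for audit
#' and a corrected working pair is supplied.
#'
#' @param metabolite Metabolite name, e.g. `"Alanine"`.
#' @param derivative Derivatization tag, e.g. `"Alanine_2TMS"`.
#' @param loss Free-text description of the neutral loss (informational).
#' @param formula Working elemental formula (string or named count vector).
#' @param m0_mz Working nominal m/z of the monoisotopic (M0) peak.
#' @param backbone 1-based indices of the metabolite carbons retained.
#' @param formula_verbatim,m0_verbatim Published values when they differ from
#'   the working ones (defaults: same as working).
#' @return An object of class `fragment_definition`.
#' @export
fragment_definition <- function(metabolite, derivative, loss, formula, m0_mz,
                                backbone, formula_verbatim = NULL,
                                m0_verbatim = NULL) {
  if (is.character(formula)) formula <- parse_formula(formula)
  formula <- check_formula(formula)
  if (is.character(formula_verbatim)) formula_verbatim <- parse_formula(formula_verbatim)
  if (is.null(formula_verbatim)) formula_verbatim <- formula
  if (is.null(m0_verbatim)) m0_verbatim <- m0_mz
  backbone <- sort(as.integer(backbone))
  nc <- metabolite_carbons()
  if (!metabolite %in% names(nc)) {
    stop("unknown metabolite: ", metabolite, call. = FALSE)
  }
  if (length(backbone) < 1L || any(backbone < 1L) || any(backbone > nc[[metabolite]])) {
    stop(metabolite, " backbone indices must lie in 1..", nc[[metabolite]],
         call. = FALSE)
  }
  if (length(backbone) > n_carbons(formula)) {
    stop("fragment cannot retain more backbone carbons than formula carbons",
         call. = FALSE)
  }
  structure(
    list(
      metabolite = metabolite,
      derivative = derivative,
      loss = loss,
      formula = formula,
      m0_mz = as.integer(m0_mz),
      backbone = backbone,
      n_backbone = length(backbone),
      formula_verbatim = formula_verbatim,
      m0_verbatim = as.integer(m0_verbatim),
      consistent = nominal_mass(formula_verbatim) == m0_verbatim,
      id = fragment_id(metabolite, backbone, m0_mz)
    ),
    class = "fragment_definition"
  )
}

fragment_id <- function(metabolite, backbone, m0_mz) {
  paste0(metabolite, "_", paste0("C", backbone, collapse = ""), "_", m0_mz)
}

#' @export
print.fragment_definition <- function(x, ...) {
  cat("<fragment> ", x$id, "  (", x$derivative, ", -", x$loss, ")\n",
      "  formula ", format_formula(x$formula), "  M0 m/z ", x$m0_mz,
      "  backbone C", paste(x$backbone, collapse = ",C"),
      if (!x$consistent) "  [published row inconsistent]" else "", "\n",
      sep = "")
  invisible(x)
}

# Registry rows: verbatim published values first, then the working
# formula/m0 where the published row is not mass-consistent.
#  - Proline C2C3C4C5_142: published formula C7H16N has nominal mass 114;
#    the working formula C7H16NSi (= derivative 259 - TMS-CO2 117) has mass 142.
#  - Glutamate C2C3C4C5: published M0 245 conflicts with its formula
#    C10H24NO2Si2 (mass 246); the body text's fragment name C2-C3-C4-C5_246
#    is used as the working M0.
#  - Glycine C2_174 (loss TMS-CO2 from the 3TMS derivative) is carried in
#    addition to the published rows because the positional combinations use it.
registry_rows <- function() {
  list(
    list("Alanine", "Alanine_2TMS", "CH3", "C8H20NO2Si2", 218L, c(1L, 2L)),
    list("Alanine", "Alanine_2TMS", "CH3, CO", "C7H20NOSi2", 190L, c(2L, 3L)),
    list("Alanine", "Alanine_2TMS", "TMS-CO2", "C5H14NSi", 116L, c(2L, 3L)),
    list("Alanine", "Alanine_2TMS", "unknown", "C4H11OSi", 103L, 1L),
    list("Glutamate", "Glutamate_3TMS", "CH3", "C13H30NO4Si3", 348L, 1:5),
    list("Glutamate", "Glutamate_3TMS", "TMS-CO2", "C10H24NO2Si2", 246L, 2:5,
         "C10H24NO2Si2", 245L),
    list("Glutamate", "Glutamate_3TMS", "TMS-CO2, TMS-OH", "C7H14NOSi", 156L, 2:5),
    list("Glutamate", "Glutamate_3TMS", "TMS-NH-C3H5-CO2-TMS", "C4H9O2Si", 117L, 1L),
    list("Glycine", "Glycine_3TMS", "CH3", "C10H26NO2Si3", 276L, c(1L, 2L)),
    list("Glycine", "Glycine_3TMS", "CH3, CO", "C9H26NOSi3", 248L, 2L),
    list("Glycine", "Glycine_3TMS", "TMS-CO2", "C7H20NSi2", 174L, 2L),
    list("Glycine", "Glycine_3TMS", "TMS-CO2, TMS-H", "C4H10NSi", 100L, 2L),
    list("Glycine", "Glycine_3TMS", "TMS-CO2, TMS-CH3", "C3H8NSi", 86L, 2L),
    list("Malate", "Malate_3TMS", "CH3", "C12H27O5Si3", 335L, 1:4),
    list("Malate", "Malate_3TMS", "C3HO3", "C10H29O2Si3", 265L, 2L),
    list("Malate", "Malate_3TMS", "TMS-OH, CH3", "C9H17O4Si2", 245L, 1:4),
    list("Malate", "Malate_3TMS", "TMS-CO2", "C9H21O3Si2", 233L, 2:4),
    list("Malate", "Malate_3TMS", "TMS-CO2, CH3, COH", "C7H17O2Si2", 189L, c(2L, 3L)),
    list("Malate", "Malate_3TMS", "C9H21O3Si2", "C4H9O2Si", 117L, 4L),
    list("Proline", "Proline_2TMS", "CH3", "C10H22NO2Si2", 244L, 1:5),
    list("Proline", "Proline_2TMS", "CH3, CO", "C9H22NOSi2", 216L, 2:5),
    list("Proline", "Proline_2TMS", "TMS-CO2", "C7H16NSi", 142L, 2:5,
         "C7H16N", 142L),
    list("Serine", "Serine_3TMS", "CH3", "C11H28NO3Si3", 306L, 1:3),
    list("Serine", "Serine_3TMS", "CH3, CO", "C10H28NO2Si3", 278L, 2:3),
    list("Serine", "Serine_3TMS", "TMS-CH2O", "C8H20NO2Si2", 218L, c(1L, 2L)),
    list("Serine", "Serine_3TMS", "TMS-CO2", "C8H22NOSi2", 204L, 2:3),
    list("Serine", "Serine_3TMS", "unknown", "C4H10NSi", 100L, 2L)
  )
}

#' Load the built-in TMS fragment registry
#'
#' Returns the full registry of mass fragments with identified carbon
#' backbones for the six supported metabolites, keyed by fragment id
#' (`"<Metabolite>_<positions>_<M0>"`, e.g. `"Glycine_C2_100"`).
#'
#' @param metabolite Optional metabolite name to subset to.
#' @return Named list of [fragment_definition()] objects.
#' @examples
#' frags <- load_fragment_table("Serine")
#' names(frags)
#' @export
load_fragment_table <- function(metabolite = NULL) {
  defs <- lapply(registry_rows(), function(r) {
    fragment_definition(r[[1]], r[[2]], r[[3]], r[[4]], r[[5]], r[[6]],
                        formula_verbatim = if (length(r) >= 7) r[[7]],
                        m0_verbatim = if (length(r) >= 8) r[[8]])
  })
  names(defs) <- vapply(defs, `[[`, character(1), "id")
  if (!is.null(metabolite)) {
    defs <- defs[vapply(defs, function(d) d$metabolite %in% metabolite, logical(1))]
  }
  defs
}

#' Audit a fragment registry for mass consistency
#'
#' Recomputes the nominal mass of every fragment's published formula and
#' compares it to the published M0 m/z. Known discrepant rows in the built-in
#' registry are reported, never silently fixed.
#'
#' @param defs Named list of fragment definitions
#'   (default: [load_fragment_table()]).
#' @return Tibble with one row per mismatch: fragment id, published formula,
#'   declared and computed masses, and the working values used instead.
#' @export
validate_fragment_table <- function(defs = load_fragment_table()) {
  rows <- lapply(defs, function(d) {
    computed <- nominal_mass(d$formula_verbatim)
    if (computed == d$m0_verbatim) return(NULL)
    tibble::tibble(
      fragment_id = d$id,
      formula_published = format_formula(d$formula_verbatim),
      m0_published = d$m0_verbatim,
      m0_computed = computed,
      formula_working = format_formula(d$formula),
      m0_working = d$m0_mz
    )
  })
  dplyr::bind_rows(rows)
}

#' Serialize / read a fragment registry as TSV
#'
#' Columns mirror the published fragment table (derivative, loss, formula,
#' m0_mz, backbone) so users can extend the registry with their own fragments.
#'
#' @param defs Named list of fragment definitions.
#' @param path File path.
#' @return `write_fragment_tsv()` returns `path` invisibly;
#'   `read_fragment_tsv()` returns a named list of fragment definitions.
#' @export
write_fragment_tsv <- function(defs, path) {
  tbl <- tibble::tibble(
    metabolite = vapply(defs, `[[`, character(1), "metabolite"),
    derivative = vapply(defs, `[[`, character(1), "derivative"),
    loss = vapply(defs, `[[`, character(1), "loss"),
    formula = vapply(defs, function(d) format_formula(d$formula), character(1)),
    m0_mz = vapply(defs, `[[`, integer(1), "m0_mz"),
    backbone = vapply(defs, function(d) paste(d$backbone, collapse = "-"), character(1))
  )
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' @rdname write_fragment_tsv
#' @export
read_fragment_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  defs <- lapply(seq_len(nrow(tbl)), function(i) {
    fragment_definition(
      tbl$metabolite[i], tbl$derivative[i], tbl$loss[i], tbl$formula[i],
      tbl$m0_mz[i], as.integer(strsplit(tbl$backbone[i], "-", fixed = TRUE)[[1]])
    )
  })
  names(defs) <- vapply(defs, `[[`, character(1), "id")
  defs
}
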
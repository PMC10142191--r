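#' Parse an elemental formula string
#'
#' Accepts both the plain dialect (`"C8H20NO2Si2"`) and the
#' underscore-subscript dialect used in fragment tables
#' (`"C_8_H_20_NO_2_Si_2"`). Only the elements occurring in TMS derivatives of
#' amino and organic acids are supported: C, H, N, O, Si.
#'
#' @param text Formula string. An omitted count means one atom.
#' @return Named integer vector of per-element atom counts, e.g.
#'   `c(C = 8, H = 20, N = 1, O = 2, Si = 2)`.
#' @examples
#' parse_formula("C_8_H_20_NO_2_Si_2")
#' parse_formula("C4H9O2Si")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("formula must be a single non-empty string", call. = FALSE)
  }
  plain <- gsub("_", "", text, fixed = TRUE)
  if (grepl("[^A-Za-z0-9]", plain)) {
    stop("malformed formula: '", text, "'", call. = FALSE)
  }
  # Si must be matched before single-letter symbols
  m <- gregexpr("(Si|C|H|N|O)([0-9]*)", plain)[[1]]
  tokens <- regmatches(plain, gregexpr("(Si|C|H|N|O)([0-9]*)", plain))[[1]]
  if (sum(attr(m, "match.length")) != nchar(plain)) {
    stop("unknown element symbol in formula: '", text, "'", call. = FALSE)
  }
  counts <- integer(0)
  for (tok in tokens) {
    sym <- sub("[0-9]*$", "", tok)
    num <- sub("^(Si|C|H|N|O)", "", tok)
    k <- if (nzchar(num)) as.integer(num) else 1L
    if (is.na(k) || k < 1L) stop("malformed count in formula: '", text, "'", call. = FALSE)
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + k
  }
  counts[counts > 0L]
}

#' Format an elemental formula as a plain string
#'
#' Inverse of [parse_formula()] (Hill-like order: C, H, then N, O, Si).
#'
#' @param f Named integer vector of atom counts.
#' @return Formula string in the plain dialect.
#' @export
format_formula <- function(f) {
  f <- check_formula(f)
  order <- c("C", "H", "N", "O", "Si")
  parts <- vapply(order[order %in% names(f)], function(el) {
    k <- f[[el]]
    if (k == 1L) el else paste0(el, k)
  }, character(1))
  paste(parts, collapse = "")
}

#' Nominal (integer) mass of an elemental formula
#'
#' Uses nominal atomic masses C = 12, H = 1, N = 14, O = 16, Si = 28, the
#' scale on which low-resolution GC-MS m/z values are reported.
#'
#' @param f Named integer vector of atom counts (see [parse_formula()]).
#' @return Integer nominal mass.
#' @examples
#' nominal_mass(parse_formula("C8H20NO2Si2")) # 218
#' @export
nominal_mass <- function(f) {
  f <- check_formula(f)
  masses <- c(C = 12L, H = 1L, N = 14L, O = 16L, Si = 28L)
  sum(masses[names(f)] * f)
}

check_formula <- function(f) {
  if (length(f) == 0L) stop("formula must contain at least one atom", call. = FALSE)
  if (is.null(names(f)) || any(!nzchar(names(f)))) {
    stop("formula must be a named count vector", call. = FALSE)
  }
  bad <- setdiff(names(f), c("C", "H", "N", "O", "Si"))
  if (length(bad)) {
    stop("unsupported element(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(f != round(f)) || any(f < 1)) {
    stop("atom counts must be positive integers", call. = FALSE)
  }
  storage.mode(f) <- "integer"
  f
}

n_carbons <- function(f) if ("C" %in% names(f)) f[["C"]] else 0L
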
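#' Natural-isotope abundance table
#'
#' Per-element distributions of nominal mass shifts (0, +1, +2 relative to the
#' lightest isotope). The 13C natural abundance defaults to 0.011 (1.1%) and
#' can be overridden; the remaining values are standard terrestrial
#' abundances rounded to the precision relevant at low mass resolution.
#'
#' @param c13 Natural 13C abundance (fraction).
#' @return Named list; each element is a numeric vector of abundances indexed
#'   by mass shift 0, 1, 2.
#' @export
isotope_table <- function(c13 = 0.011) {
  stopifnot(c13 > 0, c13 < 1)
  list(
    C  = c(1 - c13, c13),
    H  = c(0.99988, 0.00012),
    N  = c(0.99636, 0.00364),
    O  = c(0.99757, 0.00038, 0.00205),
    Si = c(0.9223, 0.0467, 0.0310)
  )
}

#' A monoisotopic table (every element a single isotope), useful to isolate
#' the backbone-carbon part of a correction.
#' @rdname isotope_table
#' @export
monoisotopic_table <- function() {
  list(C = 1, H = 1, N = 1, O = 1, Si = 1)
}

conv <- function(a, b) {
  if (length(a) == 1L && a == 1) return(b)
  if (length(b) == 1L && b == 1) return(a)
  convolve(a, rev(b), type = "open")
}

conv_pow <- function(d, k) {
  out <- 1
  for (i in seq_len(k)) out <- conv(out, d)
  out
}

#' Mass-shift distribution of a formula's natural isotopes
#'
#' Convolves the per-atom isotope shift distributions of every atom in the
#' formula, excluding `exclude_backbone_c` carbon atoms (the metabolite
#' backbone carbons, whose isotopic state is what labeling experiments
#' measure and must therefore not be corrected away here).
#'
#' @param f Elemental formula (string or named count vector).
#' @param exclude_backbone_c Number of carbon atoms to exclude.
#' @param table Isotope table, see [isotope_table()].
#' @param window If non-`NULL`, truncate the returned vector to shifts
#'   `0..window` (not renormalized). `NULL` returns the full distribution.
#' @return Probability vector over mass shifts starting at 0.
#' @examples
#' shift_distribution("Si", window = 2)
#' @export
shift_distribution <- function(f, exclude_backbone_c = 0L,
                               table = isotope_table(), window = NULL) {
  if (is.character(f)) f <- parse_formula(f)
  f <- check_formula(f)
  if (!is.null(window) && window < 0) stop("window must be >= 0", call. = FALSE)
  nc <- n_carbons(f)
  if (exclude_backbone_c > nc) {
    stop("cannot exclude more carbons than the formula contains", call. = FALSE)
  }
  counts <- f
  if (nc > 0L) counts[["C"]] <- nc - as.integer(exclude_backbone_c)
  counts <- counts[counts > 0L]
  out <- 1
  for (el in names(counts)) {
    out <- conv(out, conv_pow(table[[el]], counts[[el]]))
  }
  out <- pmax(as.numeric(out), 0)
  if (!is.null(window)) out <- c(out, numeric(max(0, window + 1L - length(out))))[seq_len(window + 1L)]
  out
}

#' Correction options
#'
#' Two modes are supported, mirroring how tailor-made 13C-PT standards and
#' tracer-labeled biological samples are handled. For PT standards only the
#' naturally occurring isotopes of non-backbone elements are corrected
#' (`correct_backbone = FALSE`), since the backbone 12C/13C pattern is fully
#' controlled. For tracer incorporation samples the backbone natural 13C
#' abundance and the tracer isotopic purity are additionally corrected
#' (`correct_backbone = TRUE`), so that natural-abundance material reads 0%
#' and maximally labeled material reads 100% enrichment. The two backbone
#' corrections are applied together or not at all.
#'
#' @param correct_backbone Apply backbone natural-abundance + tracer-purity
#'   correction?
#' @param tracer_purity Fraction of tracer-designated carbon positions that
#'   are actually 13C (default 0.99, typical of U-13C tracers).
#' @return List of class `correction_options`.
#' @export
correction_options <- function(correct_backbone = FALSE, tracer_purity = 0.99) {
  stopifnot(tracer_purity > 0, tracer_purity <= 1)
  structure(list(correct_backbone = isTRUE(correct_backbone),
                 tracer_purity = tracer_purity),
            class = "correction_options")
}

# Full (untruncated) measured-cluster pattern of the pure j-labeled
# isotopologue of a fragment: non-backbone natural isotopes, convolved --
# when backbone correction is active -- with Binom(j, purity) over the j
# tracer carbons (12C impurity = mass deficit) and Binom(n - j, c13) over the
# unlabeled backbone carbons (natural 13C = mass surplus). Without backbone
# correction the j labeled carbons contribute exactly +j mass units.
isotopologue_pattern <- function(frag, j, table = isotope_table(),
                                 opts = correction_options()) {
  n <- frag$n_backbone
  stopifnot(j >= 0, j <= n)
  base <- shift_distribution(frag$formula, exclude_backbone_c = n, table = table)
  if (opts$correct_backbone) {
    c13 <- if (length(table$C) > 1) table$C[2] else 0
    tracer <- dbinom(0:j, j, opts$tracer_purity)
    natural <- dbinom(0:(n - j), n - j, c13)
    conv(conv(base, tracer), natural)
  } else {
    c(numeric(j), base)
  }
}

#' Build the isotopologue correction matrix of a fragment
#'
#' Column `j` (0-based) holds the predicted measured isotopic-cluster pattern
#' of the pure j-labeled carbon isotopologue over the cluster window
#' M0..Mn (n = number of backbone carbons), truncated to that window.
#' Correcting raw areas then amounts to solving `raw = M %*% cid` for the
#' carbon isotopologue distribution `cid`.
#'
#' @param frag A [fragment_definition()].
#' @param table Isotope table.
#' @param opts [correction_options()].
#' @return `(n+1) x (n+1)` matrix of class `correction_matrix`.
#' @export
build_correction_matrix <- function(frag, table = isotope_table(),
                                    opts = correction_options()) {
  n <- frag$n_backbone
  M <- vapply(0:n, function(j) {
    p <- isotopologue_pattern(frag, j, table, opts)
    c(p, numeric(max(0, n + 1L - length(p))))[seq_len(n + 1L)]
  }, numeric(n + 1L))
  dimnames(M) <- list(paste0("M", 0:n), paste0("M", 0:n))
  structure(M, class = c("correction_matrix", "matrix", "array"),
            fragment_id = frag$id, options = opts)
}

# Lawson-Hanson active-set non-negative least squares. Problems here are
# tiny ((n+1) <= 6 columns) and near lower-triangular, so convergence is
# immediate; no installed package exposes an NNLS solver.
nnls_fit <- function(A, b, tol = 1e-12) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- as.numeric(crossprod(A, b - A %*% x))
  outer <- 0L
  while (any(!passive) && any(w[!passive] > tol) && outer < 10L * n) {
    outer <- outer + 1L
    cand <- which(!passive)
    j <- cand[which.max(w[cand])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      s[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      s[is.na(s)] <- 0
      if (all(s[passive] > tol)) {
        x <- s
        break
      }
      viol <- passive & s <= tol
      alpha <- min(x[viol] / (x[viol] - s[viol]))
      x <- x + alpha * (s - x)
      passive <- passive & x > tol
      x[!passive] <- 0
    }
    w <- as.numeric(crossprod(A, b - A %*% x))
  }
  pmax(x, 0)
}

#' Correct raw isotopic-cluster areas to a carbon isotopologue distribution
#'
#' Solves `raw ~ M %*% x` with `x >= 0` by non-negative least squares and
#' normalizes the solution to sum to one. NNLS (rather than matrix inversion)
#' prevents the small negative fractions that plain inversion produces on
#' noisy clusters.
#'
#' @param raw Numeric vector of raw areas, M0..Mn (length `n+1`).
#' @param M Correction matrix from [build_correction_matrix()].
#' @return List of class `cid_vector`: `fractions` (M0..Mn, sums to 1),
#'   `residual` (relative fit residual), `n` (backbone carbons).
#' @export
correct_areas <- function(raw, M) {
  n <- ncol(M) - 1L
  if (length(raw) != n + 1L) {
    stop("raw cluster must have exactly ", n + 1L, " areas (M0..M", n, "), got ",
         length(raw), call. = FALSE)
  }
  if (any(raw < 0)) stop("raw areas must be non-negative", call. = FALSE)
  if (all(raw == 0)) stop("raw cluster is all zero", call. = FALSE)
  x <- nnls_fit(unclass(M), raw)
  if (sum(x) <= 0) stop("correction produced an all-zero solution", call. = FALSE)
  residual <- sqrt(sum((raw - as.numeric(unclass(M) %*% x))^2)) / sqrt(sum(raw^2))
  fr <- x / sum(x)
  structure(list(fractions = setNames(fr, paste0("M", 0:n)),
                 residual = residual, n = n),
            class = "cid_vector")
}

#' @export
print.cid_vector <- function(x, ...) {
  cat("<cid> n =", x$n, " residual =", signif(x$residual, 3), "\n")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Fractional mean 13C enrichment of a CID
#'
#' The average labeled fraction per backbone carbon,
#' `sum(i * Mi) / n` over isotopologue fractions M0..Mn.
#'
#' @param cid A `cid_vector` from [correct_areas()], or a plain numeric
#'   vector of isotopologue fractions M0..Mn.
#' @param n Number of backbone carbons (inferred from a `cid_vector`).
#' @return Fraction in `[0, 1]`.
#' @examples
#' mean_enrichment(c(0.25, 0.5, 0.25)) # 0.5
#' @export
mean_enrichment <- function(cid, n = NULL) {
  fr <- if (inherits(cid, "cid_vector")) cid$fractions else as.numeric(cid)
  if (is.null(n)) n <- length(fr) - 1L
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (length(fr) != n + 1L) stop("CID must have length n + 1", call. = FALSE)
  sum((seq_along(fr) - 1L) * fr) / n
}
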
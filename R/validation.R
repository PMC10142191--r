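#' Expected CID of a 13C-PT standard fragment
#'
#' A 13C-PT standard labels every carbon independently with probability 0.5,
#' so an n-carbon fragment has the binomial CID `choose(n, i) / 2^n`.
#' Rescaling by `2^n` recovers the integer Pascal's-triangle row, the form in
#' which measured standard CIDs are conventionally compared.
#'
#' @param n Number of backbone carbons (>= 1).
#' @return List of class `expected_cid`: `n`, `fractions` (M0..Mn) and
#'   `rescaled` (integer Pascal coefficients).
#' @examples
#' expected_binomial_cid(2)$rescaled # 1 2 1
#' @export
expected_binomial_cid <- function(n) {
  if (n < 1 || n != round(n)) stop("n must be a positive integer", call. = FALSE)
  fractions <- dbinom(0:n, n, 0.5)
  structure(list(n = as.integer(n),
                 fractions = setNames(fractions, paste0("M", 0:n)),
                 rescaled = as.integer(round(fractions * 2^n))),
            class = "expected_cid")
}

#' 95% confidence interval of replicate measurements
#'
#' `mean +/- 1.96 * SD / sqrt(k)` with the sample (k - 1 denominator) SD:
#' the normal-approximation interval used to compare measured standard values
#' with their expectation.
#'
#' @param values Numeric vector of replicate measurements (k >= 2).
#' @return Named numeric vector `c(lower, upper)`, with attributes `mean`
#'   and `sd`.
#' @export
ci95 <- function(values) {
  values <- values[!is.na(values)]
  k <- length(values)
  if (k < 2) stop("at least 2 replicate values required", call. = FALSE)
  m <- mean(values)
  s <- sd(values)
  half <- 1.96 * s / sqrt(k)
  structure(c(lower = m - half, upper = m + half), mean = m, sd = s, k = k)
}

#' Flag a measurement as biased against its expected value
#'
#' A fragment isotopologue, fragment mean enrichment, or calculated
#' positional enrichment is flagged biased when the expected value falls
#' outside the 95% confidence interval of the replicate measurements.
#'
#' @param measured Numeric vector of replicate measurements.
#' @param expected Expected (theoretical) value.
#' @param id Optional identifier carried into the verdict.
#' @param tol Absolute numerical tolerance added to the interval, so that the
#'   degenerate zero-width interval of noiseless replicates does not flag
#'   floating-point rounding as bias.
#' @return One-row tibble: id, mean, sd, k, lower, upper, expected, biased.
#' @export
flag_bias <- function(measured, expected, id = NA_character_, tol = 1e-9) {
  ci <- ci95(measured)
  tibble::tibble(
    id = id,
    mean = attr(ci, "mean"),
    sd = attr(ci, "sd"),
    k = attr(ci, "k"),
    lower = ci[["lower"]],
    upper = ci[["upper"]],
    expected = expected,
    biased = expected < ci[["lower"]] - tol | expected > ci[["upper"]] + tol
  )
}

#' Accuracy report for a 13C-PT standard dataset
#'
#' Runs the PT-mode correction on simulated (or measured) 13C-PT standard
#' samples and evaluates, against the binomial expectation: each fragment's
#' CID isotopologue by isotopologue, each fragment's mean 13C enrichment
#' (expected 0.5), and each positional combination (expected 0.5). Bias flags
#' use the 95% confidence interval across replicates.
#'
#' @param samples List of `simulated_sample` objects (PT design) or the
#'   result of [run_pipeline()] on such samples.
#' @param registry Fragment registry.
#' @param combinations Positional combinations to evaluate.
#' @param table Isotope table.
#' @return List of class `pt_validation_report` with tibbles `cid`
#'   (per fragment x isotopologue, incl. Pascal-rescaled means), `enrichment`
#'   (per fragment) and `positional` (per combination), each with a `biased`
#'   flag column.
#' @export
validation_report <- function(samples, registry = load_fragment_table(),
                              combinations = published_combinations(registry),
                              table = isotope_table()) {
  res <- if (inherits(samples, "posenrich_results")) samples else
    run_pipeline(samples,
                 config = pipeline_config(correct_backbone = FALSE,
                                          registry = registry, table = table,
                                          combinations = combinations,
                                          compare = FALSE))
  enr <- res$enrichments

  cid_rows <- enr |>
    dplyr::distinct(.data$sample_id, .data$fragment_id, .data$isotopologue,
                    .data$isotopologue_fraction, .data$n_backbone) |>
    dplyr::group_by(.data$fragment_id, .data$isotopologue, .data$n_backbone) |>
    dplyr::group_split()
  cid <- dplyr::bind_rows(lapply(cid_rows, function(g) {
    n <- g$n_backbone[1]
    i <- g$isotopologue[1]
    expected <- expected_binomial_cid(n)$fractions[[i + 1L]]
    v <- flag_bias(g$isotopologue_fraction, expected, g$fragment_id[1])
    v$isotopologue <- i
    v$rescaled_mean <- v$mean * 2^n
    v$rescaled_expected <- expected * 2^n
    v
  }))

  enr_groups <- enr |>
    dplyr::distinct(.data$sample_id, .data$fragment_id, .data$mean_enrichment) |>
    dplyr::group_by(.data$fragment_id) |>
    dplyr::group_split()
  enrichment <- dplyr::bind_rows(lapply(enr_groups, function(g) {
    flag_bias(g$mean_enrichment, 0.5, g$fragment_id[1])
  }))

  pos_groups <- res$positional |>
    dplyr::group_by(.data$metabolite, .data$position, .data$method) |>
    dplyr::group_split()
  positional <- dplyr::bind_rows(lapply(pos_groups, function(g) {
    v <- flag_bias(g$value, 0.5,
                   paste(g$metabolite[1], g$position[1], g$method[1], sep = "_"))
    v$metabolite <- g$metabolite[1]
    v$position <- g$position[1]
    v$method <- g$method[1]
    v$validated <- g$validated[1]
    v
  }))

  structure(list(cid = cid, enrichment = enrichment, positional = positional),
            class = "pt_validation_report")
}

#' @export
print.pt_validation_report <- function(x, ...) {
  cat("<13C-PT validation report>\n")
  cat(" fragments flagged (mean enrichment):",
      sum(x$enrichment$biased), "/", nrow(x$enrichment), "\n")
  cat(" isotopologues flagged:", sum(x$cid$biased), "/", nrow(x$cid), "\n")
  cat(" positional combinations flagged:",
      sum(x$positional$biased), "/", nrow(x$positional), "\n")
  invisible(x)
}

#' Bar-chart of expected vs measured CID per fragment
#'
#' Optional plot hook (requires ggplot2) mirroring the conventional
#' expected-vs-measured CID bar charts for standard evaluations.
#'
#' @param report A `pt_validation_report`.
#' @param metabolite Optional metabolite to subset to (by fragment id prefix).
#' @return A ggplot object.
#' @export
plot_cid_report <- function(report, metabolite = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  d <- report$cid
  if (!is.null(metabolite)) d <- d[startsWith(d$id, metabolite), ]
  long <- dplyr::bind_rows(
    tibble::tibble(id = d$id, isotopologue = d$isotopologue,
                   what = "expected", value = d$expected, sd = 0),
    tibble::tibble(id = d$id, isotopologue = d$isotopologue,
                   what = "measured", value = d$mean, sd = d$sd)
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$isotopologue), y = .data$value, fill = .data$what)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$sd,
                                        ymax = .data$value + .data$sd),
                           position = ggplot2::position_dodge(0.9), width = 0.3) +
    ggplot2::facet_wrap(~id) +
    ggplot2::labs(x = "isotopologue (Mi)", y = "fraction", fill = NULL)
}
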
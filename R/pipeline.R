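#' Pipeline configuration
#'
#' @param correct_backbone Apply the backbone natural-abundance +
#'   tracer-purity correction (tracer experiments) or not (13C-PT standards).
#' @param tracer_purity Tracer isotopic purity (default 0.99).
#' @param combinations Positional combinations to apply.
#' @param registry Fragment registry.
#' @param table Isotope table.
#' @param compare Run between-condition comparisons when the sample metadata
#'   contains exactly two conditions?
#' @param alpha Significance threshold for the rank-sum comparisons.
#' @param residual_warn Relative correction-residual level above which a
#'   warning is emitted (poor fit usually means a contaminated cluster).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(correct_backbone = TRUE, tracer_purity = 0.99,
                            registry = load_fragment_table(),
                            combinations = published_combinations(registry),
                            table = isotope_table(), compare = TRUE,
                            alpha = 0.05, residual_warn = 1e-3) {
  structure(list(
    opts = correction_options(correct_backbone, tracer_purity),
    combinations = combinations, registry = registry, table = table,
    compare = compare, alpha = alpha, residual_warn = residual_warn
  ), class = "pipeline_config")
}

#' Read a per-sample Name/Area table
#'
#' Reads the tabular GC-MS dialect consumed by the pipeline: a TSV or CSV
#' file with a column `Name` (fragment id, spelled exactly as in the
#' registry, repeated over the cluster's rows in ascending m/z order) and a
#' column `Area` (raw integrated intensity of each cluster m/z). A fragment's
#' cluster must have exactly `n_backbone + 1` rows (M0..Mn). Unknown names
#' are reported together with the closest registry spelling.
#'
#' @param path File path (TSV or CSV; delimiter auto-detected).
#' @param registry Fragment registry.
#' @param sample_id Sample identifier (default: file name without extension).
#' @param condition,time_h,replicate Optional sample metadata.
#' @return Object of class `area_table` usable in [run_pipeline()].
#' @export
read_area_table <- function(path, registry = load_fragment_table(),
                            sample_id = sub("\\.[^.]*$", "", basename(path)),
                            condition = NA_character_, time_h = NA_real_,
                            replicate = NA_integer_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- suppressMessages(
    readr::read_delim(path, show_col_types = FALSE, progress = FALSE))
  missing_cols <- setdiff(c("Name", "Area"), names(tbl))
  if (length(missing_cols)) {
    stop("missing required column(s) in ", basename(path), ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(tbl$Area) || any(is.na(tbl$Area)) || any(tbl$Area < 0)) {
    stop("Area must be non-negative numbers in ", basename(path), call. = FALSE)
  }
  unknown <- setdiff(unique(tbl$Name), names(registry))
  if (length(unknown)) {
    hints <- vapply(unknown, function(u) {
      names(registry)[which.min(adist(u, names(registry)))]
    }, character(1))
    stop("unknown fragment name(s) in ", basename(path), ": ",
         paste0("'", unknown, "' (closest registry key: '", hints, "')",
                collapse = "; "), call. = FALSE)
  }
  counts <- table(tbl$Name)
  for (nm in names(counts)) {
    expect <- registry[[nm]]$n_backbone + 1L
    if (counts[[nm]] != expect) {
      stop("fragment ", nm, " has ", counts[[nm]], " cluster rows, expected ",
           expect, " (M0..M", expect - 1L, ")", call. = FALSE)
    }
  }
  structure(list(sample_id = sample_id, condition = condition, time_h = time_h,
                 replicate = replicate, areas = tbl[, c("Name", "Area")]),
            class = "area_table")
}

#' Run the end-to-end labeling workflow
#'
#' For each sample: correct every fragment's raw cluster to a carbon
#' isotopologue distribution and mean 13C enrichment; apply the positional
#' combinations; and, when the samples span exactly two conditions, compare
#' them per time point with a two-sided Wilcoxon-Mann-Whitney test (with a
#' Shapiro-Wilk normality check logged per group). Zero-area clusters are
#' dropped with a warning. The pipeline is a pure function of its inputs.
#'
#' @param samples List of `simulated_sample` or `area_table` objects.
#' @param config A [pipeline_config()].
#' @return List of class `posenrich_results` with tibbles `enrichments`
#'   (long: one row per fragment x isotopologue), `positional` (one row per
#'   combination x sample) and `comparisons` (one row per comparison;
#'   empty when not applicable).
#' @export
run_pipeline <- function(samples, config = pipeline_config()) {
  stopifnot(length(samples) >= 1L)
  matrices <- list()
  enr_rows <- list()
  pos_rows <- list()
  for (s in samples) {
    fr_ids <- unique(s$areas$Name)
    enr_vec <- c()
    for (fid in fr_ids) {
      frag <- config$registry[[fid]]
      if (is.null(frag)) stop("sample ", s$sample_id,
                              " contains unknown fragment ", fid, call. = FALSE)
      raw <- s$areas$Area[s$areas$Name == fid]
      if (all(raw == 0)) {
        warning("dropping all-zero cluster ", fid, " in sample ", s$sample_id,
                call. = FALSE)
        next
      }
      if (is.null(matrices[[fid]])) {
        matrices[[fid]] <- build_correction_matrix(frag, config$table, config$opts)
      }
      cid <- correct_areas(raw, matrices[[fid]])
      if (cid$residual > config$residual_warn) {
        warning(sprintf("high correction residual (%.2g) for %s in %s",
                        cid$residual, fid, s$sample_id), call. = FALSE)
      }
      me <- mean_enrichment(cid)
      enr_vec[fid] <- me
      enr_rows[[length(enr_rows) + 1L]] <- tibble::tibble(
        sample_id = s$sample_id, condition = s$condition, time_h = s$time_h,
        replicate = s$replicate, metabolite = frag$metabolite,
        fragment_id = fid, n_backbone = frag$n_backbone,
        isotopologue = 0:frag$n_backbone,
        isotopologue_fraction = as.numeric(cid$fractions),
        mean_enrichment = me, residual = cid$residual
      )
    }
    for (spec in config$combinations) {
      if (!all(names(spec$weights) %in% names(enr_vec))) next
      row <- apply_combination(spec, enr_vec)
      row$sample_id <- s$sample_id
      row$condition <- s$condition
      row$time_h <- s$time_h
      row$replicate <- s$replicate
      pos_rows[[length(pos_rows) + 1L]] <- row
    }
  }
  enrichments <- dplyr::bind_rows(enr_rows)
  positional <- dplyr::bind_rows(pos_rows)
  comparisons <- tibble::tibble()
  conds <- unique(enrichments$condition)
  conds <- conds[!is.na(conds)]
  if (isTRUE(config$compare) && length(conds) == 2L) {
    comparisons <- compare_conditions(enrichments, positional, conds,
                                      config$alpha)
  }
  structure(list(enrichments = enrichments, positional = positional,
                 comparisons = comparisons),
            class = "posenrich_results")
}

#' @export
print.posenrich_results <- function(x, ...) {
  cat("<posenrich results>\n",
      " enrichments: ", nrow(x$enrichments), " rows (",
      length(unique(x$enrichments$sample_id)), " samples)\n",
      " positional:  ", nrow(x$positional), " rows\n",
      " comparisons: ", nrow(x$comparisons), " rows\n", sep = "")
  invisible(x)
}

shapiro_p <- function(v) {
  if (length(v) < 3 || sd(v) == 0) return(NA_real_)
  tryCatch(shapiro.test(v)$p.value, error = function(e) NA_real_)
}

compare_conditions <- function(enrichments, positional, conds, alpha) {
  rows <- list()
  frag_level <- enrichments |>
    dplyr::distinct(.data$sample_id, .data$condition, .data$time_h,
                    .data$metabolite, .data$fragment_id, .data$mean_enrichment)
  grids <- list(
    list(data = frag_level, id_cols = c("metabolite", "fragment_id"),
         value = "mean_enrichment", level = "fragment"),
    list(data = positional, id_cols = c("metabolite", "position", "method"),
         value = "value", level = "position")
  )
  for (g in grids) {
    if (!nrow(g$data)) next
    key <- interaction(c(g$data[g$id_cols], g$data["time_h"]), drop = TRUE)
    for (grp in split(g$data, key)) {
      a <- grp[[g$value]][grp$condition == conds[1]]
      b <- grp[[g$value]][grp$condition == conds[2]]
      if (length(a) < 3 || length(b) < 3) next
      cmp <- compare_groups(a, b)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        level = g$level,
        metabolite = grp$metabolite[1],
        id = if (g$level == "fragment") grp$fragment_id[1] else
          paste(grp$position[1], grp$method[1], sep = "_"),
        time_h = grp$time_h[1],
        condition_a = conds[1], condition_b = conds[2],
        n_a = length(a), n_b = length(b),
        mean_a = mean(a), mean_b = mean(b),
        shapiro_p_a = shapiro_p(a), shapiro_p_b = shapiro_p(b),
        statistic = cmp$statistic, p_value = cmp$p_value,
        method = cmp$method, significant = cmp$p_value < alpha
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Two-sided Wilcoxon-Mann-Whitney comparison of two groups
#'
#' Exact two-sided rank-sum p-value for small groups (both sizes <= 8 and no
#' ties); mid-rank normal approximation with continuity correction otherwise.
#'
#' @param a,b Numeric vectors of group values.
#' @return One-row tibble: n_a, n_b, statistic (Mann-Whitney U of group a),
#'   p_value, method ("exact" or "normal").
#' @export
compare_groups <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty group", call. = FALSE)
  ties <- any(duplicated(c(a, b)))
  exact <- max(length(a), length(b)) <= 8 && !ties
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE))
  tibble::tibble(
    n_a = length(a), n_b = length(b),
    statistic = unname(wt$statistic),
    p_value = min(1, wt$p.value),
    method = if (exact) "exact" else "normal"
  )
}
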
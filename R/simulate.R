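#' Ground-truth positional labeling state of a metabolite
#'
#' Either independent per-position 13C probabilities (`p`), or an explicit
#' distribution over all `2^N` positional isotopomers (`isotopomers`, named by
#' 0/1 strings, position 1 first, summing to 1). The tailor-made 13C-PT
#' standards correspond to independent `p = 0.5` at every position: a
#' binomial carbon isotopologue distribution with equal proportions of every
#' isotopomer within each isotopologue.
#'
#' @param metabolite Metabolite name.
#' @param p Per-position 13C probabilities (length = carbon count).
#' @param isotopomers Named probability vector over 0/1 pattern strings,
#'   e.g. `c("00" = 0.5, "10" = 0.5)`. Exactly one of `p`/`isotopomers`.
#' @return Object of class `label_state`.
#' @export
label_state <- function(metabolite, p = NULL, isotopomers = NULL) {
  n <- metabolite_carbons()[[metabolite]]
  if (is.null(n)) stop("unknown metabolite: ", metabolite, call. = FALSE)
  if (is.null(p) == is.null(isotopomers)) {
    stop("supply exactly one of p or isotopomers", call. = FALSE)
  }
  if (!is.null(p)) {
    stopifnot(length(p) == n, all(p >= 0), all(p <= 1))
  } else {
    stopifnot(all(nchar(names(isotopomers)) == n),
              abs(sum(isotopomers) - 1) < 1e-9, all(isotopomers >= 0))
  }
  structure(list(metabolite = metabolite, p = p, isotopomers = isotopomers),
            class = "label_state")
}

#' 13C-PT standard labeling state (independent p = 0.5 at every position)
#' @rdname label_state
#' @export
pt_label_state <- function(metabolite) {
  label_state(metabolite, p = rep(0.5, metabolite_carbons()[[metabolite]]))
}

#' Carbon isotopologue distribution of a fragment under a labeling state
#'
#' Distribution of the number of labeled carbons among the fragment's
#' backbone subset: a Poisson-binomial for independent per-position
#' probabilities, or a marginalization of the explicit isotopomer
#' distribution.
#'
#' @param state A [label_state()].
#' @param frag A [fragment_definition()] of the same metabolite.
#' @return Numeric CID vector M0..Mn (n = fragment backbone size).
#' @export
fragment_cid_from_positions <- function(state, frag) {
  if (state$metabolite != frag$metabolite) {
    stop("labeling state is for ", state$metabolite, ", fragment for ",
         frag$metabolite, call. = FALSE)
  }
  n <- frag$n_backbone
  if (!is.null(state$p)) {
    cid <- 1
    for (i in frag$backbone) {
      cid <- conv(cid, c(1 - state$p[i], state$p[i]))
    }
    cid <- as.numeric(cid)
    cid <- c(cid, numeric(n + 1L - length(cid)))
  } else {
    cid <- numeric(n + 1L)
    for (pat in names(state$isotopomers)) {
      bits <- as.integer(strsplit(pat, "")[[1]])
      k <- sum(bits[frag$backbone])
      cid[k + 1L] <- cid[k + 1L] + state$isotopomers[[pat]]
    }
  }
  setNames(pmax(cid, 0), paste0("M", 0:n))
}

#' Co-eluting contaminant ion specification
#'
#' Models the documented classes of analytical bias: a contaminant ion whose
#' own natural-isotope cluster overlaps the fragment's, either isobaric with
#' M0 (offset 0, e.g. the mass interfering with the glutamate C1 / malate C4
#' fragment at m/z 117) or shifted upward (e.g. the co-eluting ion at
#' m/z 218 contaminating the proline C2-C3-C4-C5 fragment at m/z 216,
#' offset +2).
#'
#' @param fragment_id Registry id of the fragment whose cluster is affected.
#' @param offset Non-negative integer m/z offset of the contaminant's M0
#'   relative to the fragment's M0.
#' @param intensity Contaminant M0 area as a fraction of the fragment's total
#'   (noiseless) cluster area.
#' @param formula Elemental formula of the contaminant ion (drives its own
#'   natural-isotope pattern).
#' @return Object of class `contaminant_spec`.
#' @export
contaminant_spec <- function(fragment_id, offset, intensity, formula) {
  stopifnot(offset >= 0, offset == round(offset), intensity >= 0)
  if (is.character(formula)) formula <- parse_formula(formula)
  structure(list(fragment_id = fragment_id, offset = as.integer(offset),
                 intensity = intensity, formula = check_formula(formula)),
            class = "contaminant_spec")
}

#' Simulate the raw isotopic-cluster areas of one fragment
#'
#' Forward model of the measurement that the correction inverts: each
#' isotopologue of the CID contributes its untruncated measured pattern
#' (natural isotopes of non-backbone elements; plus, in tracer mode, binomial
#' tracer purity on labeled and natural 13C on unlabeled backbone carbons),
#' contaminant clusters are added, and multiplicative log-normal noise with
#' the stated CV is applied. Deterministic for a fixed `seed`.
#'
#' @param frag A [fragment_definition()].
#' @param cid CID vector M0..Mn (fractions summing to 1).
#' @param table Isotope table.
#' @param opts [correction_options()]; `correct_backbone = FALSE` simulates a
#'   PT-standard-style fully controlled backbone, `TRUE` simulates tracer
#'   labeling at `tracer_purity` with natural 13C on unlabeled positions.
#' @param contaminants List of [contaminant_spec()] targeting this fragment.
#' @param noise_cv Coefficient of variation of multiplicative noise (0 = none).
#' @param total_area Total (untruncated, pre-contaminant) cluster area.
#' @param seed Optional integer seed.
#' @param truncate If `TRUE` (default) return the measured window M0..Mn;
#'   otherwise the full untruncated cluster.
#' @return Numeric area vector.
#' @export
simulate_fragment_areas <- function(frag, cid, table = isotope_table(),
                                    opts = correction_options(),
                                    contaminants = list(), noise_cv = 0,
                                    total_area = 1e6, seed = NULL,
                                    truncate = TRUE) {
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  n <- frag$n_backbone
  stopifnot(length(cid) == n + 1L, abs(sum(cid) - 1) < 1e-6)
  if (!is.null(seed)) set.seed(seed)
  full <- numeric(0)
  for (j in 0:n) {
    pat <- cid[[j + 1L]] * isotopologue_pattern(frag, j, table, opts)
    full <- add_at(full, pat, 0L)
  }
  full <- total_area * full
  for (ct in contaminants) {
    if (!identical(ct$fragment_id, frag$id)) next
    pat <- shift_distribution(ct$formula, table = table)
    full <- add_at(full, ct$intensity * total_area * pat, ct$offset)
  }
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    full <- full * rlnorm(length(full), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  if (truncate) {
    full <- c(full, numeric(max(0, n + 1L - length(full))))[seq_len(n + 1L)]
    names(full) <- paste0("M", 0:n)
  }
  full
}

add_at <- function(acc, vec, offset) {
  len <- max(length(acc), offset + length(vec))
  out <- c(acc, numeric(len - length(acc)))
  idx <- offset + seq_along(vec)
  out[idx] <- out[idx] + vec
  out
}

new_simulated_sample <- function(sample_id, condition, time_h, replicate,
                                 areas, truth) {
  structure(list(sample_id = sample_id, condition = condition,
                 time_h = time_h, replicate = replicate,
                 areas = areas, truth = truth),
            class = "simulated_sample")
}

#' @export
print.simulated_sample <- function(x, ...) {
  cat("<sample> ", x$sample_id, "  condition=", x$condition,
      " t=", x$time_h, "h rep=", x$replicate, "  (", nrow(x$areas),
      " area rows)\n", sep = "")
  invisible(x)
}

simulate_sample <- function(sample_id, condition, time_h, replicate, states,
                            registry, table, opts, contaminants, noise_cv,
                            total_area) {
  rows <- list()
  for (st in states) {
    for (frag in registry[vapply(registry, function(d)
      d$metabolite == st$metabolite, logical(1))]) {
      cid <- fragment_cid_from_positions(st, frag)
      areas <- simulate_fragment_areas(frag, cid, table, opts, contaminants,
                                       noise_cv, total_area)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        Name = frag$id, mz = frag$m0_mz + 0:frag$n_backbone,
        Area = as.numeric(areas)
      )
    }
  }
  new_simulated_sample(sample_id, condition, time_h, replicate,
                       dplyr::bind_rows(rows), states)
}

#' Simulate a 13C-PT standard dataset
#'
#' Generates raw area tables for tailor-made binomial 13C-PT standards:
#' every backbone position of every metabolite labeled independently with
#' probability 0.5, so that every fragment has a binomial CID and a
#' fractional mean 13C enrichment of exactly 0.5. Simulated in PT mode
#' (fully controlled backbone, no tracer-purity/natural-abundance terms).
#'
#' @param metabolites Metabolite names (default: all six).
#' @param n_replicates Number of replicates (default 4, as in the standard
#'   evaluation design).
#' @param noise_cv Multiplicative noise CV (default 0 = noiseless).
#' @param seed Optional integer seed.
#' @param contaminants Optional list of [contaminant_spec()] to inject biases.
#' @param registry Fragment registry.
#' @param table Isotope table.
#' @param total_area Per-fragment total cluster area.
#' @return List of `simulated_sample` objects with stored ground truth.
#' @export
simulate_pt_standard_dataset <- function(metabolites = names(metabolite_carbons()),
                                         n_replicates = 4, noise_cv = 0,
                                         seed = NULL, contaminants = list(),
                                         registry = load_fragment_table(),
                                         table = isotope_table(),
                                         total_area = 1e6) {
  if (!is.null(seed)) set.seed(seed)
  states <- lapply(metabolites, pt_label_state)
  opts <- correction_options(correct_backbone = FALSE)
  lapply(seq_len(n_replicates), function(r) {
    simulate_sample(sprintf("PT_rep%d", r), "PT", 0, r, states, registry,
                    table, opts, contaminants, noise_cv, total_area)
  })
}

#' Default U-13C-pyruvate labeling kinetics scenario
#'
#' A stated-world time course for U-13C-pyruvate incorporation into leaf
#' discs under light and dark, encoding the qualitative biology the method is
#' used to detect: photorespiratory serine labeled only at C2 (and glycine at
#' C2) in the light; glutamate C2-C5 labeled in both conditions with C1
#' labeling appearing in the dark at late time points (cyclic TCA turnover);
#' malate C1 similar between conditions. All samples start at zero labeling
#' at t = 0.
#'
#' @return Tibble with columns condition, time_h, metabolite and a `state`
#'   list-column of [label_state()] objects.
#' @export
default_kinetics_scenario <- function() {
  times <- c(0, 1, 2, 4, 6)
  ramp <- function(top) top * (1 - exp(-times / 2.5))
  ser_light <- ramp(0.30); gly_light <- ramp(0.32)
  glu_rest <- ramp(0.18); glu_c1_dark <- ramp(0.14)
  mal_c1 <- ramp(0.12); mal_c4_light <- ramp(0.16); mal_c4_dark <- ramp(0.08)
  rows <- list()
  for (i in seq_along(times)) {
    t <- times[i]
    for (cond in c("light", "dark")) {
      light <- cond == "light"
      rows[[length(rows) + 1L]] <- tibble::tibble(
        condition = cond, time_h = t,
        metabolite = c("Glycine", "Serine", "Glutamate", "Malate"),
        state = list(
          label_state("Glycine", p = c(0, if (light) gly_light[i] else 0)),
          label_state("Serine", p = c(0, if (light) ser_light[i] else 0, 0)),
          label_state("Glutamate", p = c(
            if (light) 0 else glu_c1_dark[i], rep(glu_rest[i], 4))),
          label_state("Malate", p = c(
            mal_c1[i], 0.02 * (t > 0), 0.02 * (t > 0),
            if (light) mal_c4_light[i] else mal_c4_dark[i]))
        )
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate a labeling kinetics experiment
#'
#' Generates light/dark x timepoint x replicate samples from a scenario of
#' ground-truth labeling states, in tracer mode (tracer purity and natural
#' 13C abundance of unlabeled backbone positions convolved into the spectra,
#' so the matching full correction recovers the ground truth).
#'
#' @param scenario Tibble as returned by [default_kinetics_scenario()].
#' @param n_replicates Replicates per condition x timepoint (default 4).
#' @param noise_cv Multiplicative noise CV (default 0.05, a typical
#'   between-replicate area CV for GC-MS).
#' @param seed Optional integer seed.
#' @param tracer_purity Tracer isotopic purity (default 0.99).
#' @param contaminants Optional list of [contaminant_spec()].
#' @param registry Fragment registry.
#' @param table Isotope table.
#' @param total_area Per-fragment total cluster area.
#' @return List of `simulated_sample` objects with stored ground truth.
#' @export
simulate_labeling_kinetics <- function(scenario = default_kinetics_scenario(),
                                       n_replicates = 4, noise_cv = 0.05,
                                       seed = NULL, tracer_purity = 0.99,
                                       contaminants = list(),
                                       registry = load_fragment_table(),
                                       table = isotope_table(),
                                       total_area = 1e6) {
  if (!is.null(seed)) set.seed(seed)
  opts <- correction_options(correct_backbone = TRUE,
                             tracer_purity = tracer_purity)
  groups <- dplyr::group_split(
    dplyr::group_by(scenario, .data$condition, .data$time_h))
  out <- list()
  for (g in groups) {
    cond <- g$condition[1]; t <- g$time_h[1]
    for (r in seq_len(n_replicates)) {
      out[[length(out) + 1L]] <- simulate_sample(
        sprintf("%s_t%g_rep%d", cond, t, r), cond, t, r, g$state, registry,
        table, opts, contaminants, noise_cv, total_area)
    }
  }
  out
}

#' Write simulated samples to per-sample Name/Area TSV files
#'
#' Emits the tabular dialect the pipeline consumes (columns `Name`, `Area`,
#' one row per cluster m/z in ascending order), one file per sample, plus a
#' ground-truth TSV of per-position labeling probabilities.
#'
#' @param samples List of `simulated_sample` objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sample_tables <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  truth <- list()
  for (s in samples) {
    path <- file.path(dir, paste0(s$sample_id, ".tsv"))
    readr::write_tsv(s$areas[, c("Name", "Area")], path)
    paths <- c(paths, path)
    for (st in s$truth) {
      if (is.null(st$p)) next
      truth[[length(truth) + 1L]] <- tibble::tibble(
        sample_id = s$sample_id, condition = s$condition, time_h = s$time_h,
        replicate = s$replicate, metabolite = st$metabolite,
        position = paste0("C", seq_along(st$p)), p = st$p
      )
    }
  }
  tpath <- file.path(dir, "ground_truth.tsv")
  readr::write_tsv(dplyr::bind_rows(truth), tpath)
  invisible(c(paths, tpath))
}
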
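#' Run the full encoding-model ladder on a session
#'
#' For every unit: builds the LFP, pathlet and spike-history feature blocks,
#' evaluates each requested feature-set ladder by nested cross-validation,
#' optionally estimates the permutation chance level of the LFP-only model,
#' and tests the nested comparisons (does adding LFP to kinematics help; does
#' adding history help; does LFP still help once kinematics and history are
#' in the model) across the unit population.
#'
#' @param session A `pp_session` from [generate_session()] or
#'   [read_session()], or a directory path containing a written session.
#' @param config A [cv_config()]; its seed controls fold assignment (shared
#'   across ladders, so comparisons are paired).
#' @param ladders Character vector of feature-set names; elements are `+`
#'   combinations of `lfp`, `kin`, `hist` (e.g. `"kin+hist+lfp"`).
#' @param comparisons List of `c(base, extended)` pairs to test; any ladder
#'   they mention is evaluated too.
#' @param n_perm Permutations for the LFP chance level; 0 skips it.
#' @param per_feature If `TRUE`, also fit one model per LFP feature per band
#'   (the phase cos/sin pair counts as one model) for the single-feature
#'   breakdown.
#' @param units Subset of unit indices (default all).
#' @return An object of class `session_report`: `pp_by_unit`,
#'   `comparisons`, optional `per_feature` tibbles and provenance.
#' @export
run_session <- function(session,
                        config = cv_config(),
                        ladders = c("lfp", "kin", "kin+hist", "kin+hist+lfp"),
                        comparisons = list(c("kin", "kin+lfp"),
                                           c("kin", "kin+hist"),
                                           c("kin+hist", "kin+hist+lfp")),
                        n_perm = 0,
                        per_feature = FALSE,
                        units = NULL) {
  if (is.character(session)) session <- read_session(session)
  session <- ensure_blocks(session)
  ladders <- union(ladders, unlist(lapply(comparisons, identity)))
  units <- units %||% seq_along(session$spikes)
  basis <- raised_cosine_basis()
  rows <- session$usable_rows
  pp_rows <- list()
  chance_rows <- list()
  cv_store <- list()
  for (u in units) {
    y <- session$spikes[[u]]
    blocks <- c(session$blocks,
                list(hist = history_columns(y, basis)))
    for (lad in ladders) {
      parts <- strsplit(lad, "+", fixed = TRUE)[[1]]
      if (!all(parts %in% names(blocks))) {
        abort(sprintf("unknown feature set '%s'", lad))
      }
      cv <- nested_cv_fit(blocks[parts], y, config, rows = rows,
                          feature_set = lad)
      cv_store[[paste(u, lad, sep = ":")]] <- cv
      pp_rows[[length(pp_rows) + 1]] <-
        tibble(unit = u, feature_set = lad, pp = cv$pp_pooled,
               pp_fold_mean = mean(cv$pp_per_fold),
               pp_fold_sd = sd(cv$pp_per_fold))
    }
    if (n_perm > 0) {
      lfp_cv <- cv_store[[paste(u, "lfp", sep = ":")]]
      alpha_u <- if (!is.null(lfp_cv)) median(lfp_cv$selected_alphas) else NULL
      ch <- chance_level(session$blocks["lfp"], y, config, n_perm = n_perm,
                         rows = rows, alpha = alpha_u)
      chance_rows[[length(chance_rows) + 1]] <-
        tibble(unit = u, feature_set = "lfp",
               chance_pp_95 = ch$threshold,
               null_pp_median = median(ch$null_pp),
               alpha = ch$alpha)
    }
  }
  pp_by_unit <- dplyr::bind_rows(pp_rows)
  chance_tbl <- if (length(chance_rows)) dplyr::bind_rows(chance_rows) else NULL
  cmp_list <- lapply(comparisons, function(pr) {
    compare_feature_sets(pp_by_unit, pr[1], pr[2],
                         n_tests = length(comparisons))
  })
  cmp_tbl <- dplyr::bind_rows(lapply(cmp_list, tidy))
  pf <- if (per_feature) {
    per_feature_pp(session, config, units = units)
  } else NULL
  structure(list(pp_by_unit = pp_by_unit,
                 chance = chance_tbl,
                 comparisons = cmp_tbl,
                 comparison_objects = cmp_list,
                 per_feature = pf,
                 cv = cv_store,
                 provenance = list(seed = config$seed,
                                   session_seed = session$seed,
                                   config = unclass(config),
                                   n_units = length(units),
                                   duration_s = session$duration_s)),
            class = "session_report")
}

ensure_blocks <- function(session) {
  if (!is.null(session$blocks) && !is.null(session$usable_rows)) {
    return(session)
  }
  lfp_block <- lfp_feature_block(session$lfp$value, session$fs_lfp)
  kin_block <- pathlet_features(session$kin)
  n <- min(nrow(lfp_block), nrow(kin_block), length(session$spikes[[1]]))
  lfp_block <- lfp_block[seq_len(n), ]
  kin_block <- kin_block[seq_len(n), ]
  session$spikes <- lapply(session$spikes,
                           function(y) binned_spikes(unclass(y)[seq_len(n)]))
  rows_ok <- usable_feature_rows(list(lfp = lfp_block, kin = kin_block))
  edge <- 2000
  session$usable_rows <- intersect((edge + 1):(n - edge), rows_ok)
  session$blocks <- list(lfp = lfp_block, kin = kin_block)
  session
}

# One model per LFP feature per band: amplitude, analytic signal (re+im),
# and for narrow bands the phase pair (cos+sin) as a single model.
per_feature_pp <- function(session, config, units) {
  bands <- lfp_bands()
  lfp_block <- session$blocks$lfp
  rows <- session$usable_rows
  out <- list()
  for (u in units) {
    y <- session$spikes[[u]]
    for (i in seq_len(nrow(bands))) {
      bn <- bands$band[i]
      groups <- list(amp = paste0(bn, "_amp"),
                     analytic = paste0(bn, c("_re", "_im")))
      if (bands$kind[i] == "narrow") {
        groups$phase <- paste0(bn, c("_cos", "_sin"))
      }
      for (gn in names(groups)) {
        cols <- c("t_ms", groups[[gn]])
        cv <- nested_cv_fit(list(lfp = lfp_block[cols]), y, config,
                            rows = rows,
                            feature_set = paste(bn, gn, sep = "_"))
        out[[length(out) + 1]] <-
          tibble(unit = u, band = bn, feature = gn, pp = cv$pp_pooled)
      }
    }
  }
  dplyr::bind_rows(out)
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("<session_report: %d units x %d feature sets>\n",
              length(unique(x$pp_by_unit$unit)),
              length(unique(x$pp_by_unit$feature_set))))
  print(dplyr::summarise(
    dplyr::group_by(x$pp_by_unit, .data$feature_set),
    mean_pp = mean(.data$pp), median_pp = median(.data$pp)))
  if (!is.null(x$comparisons) && nrow(x$comparisons)) {
    cat("comparisons:\n")
    print(x$comparisons)
  }
  invisible(x)
}

#' Write a session report as CSV/JSON tables
#'
#' Emits `pp_by_unit.csv`, `comparisons.json`, optionally
#' `per_feature_pp.csv` and `chance.csv`, plus `provenance.json` carrying
#' the seeds and configuration so every number is reproducible.
#'
#' @param report A `session_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_session_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$pp_by_unit, file.path(dir, "pp_by_unit.csv"))
  jsonlite::write_json(report$comparisons, file.path(dir, "comparisons.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(report$per_feature)) {
    readr::write_csv(report$per_feature, file.path(dir, "per_feature_pp.csv"))
  }
  if (!is.null(report$chance)) {
    readr::write_csv(report$chance, file.path(dir, "chance.csv"))
  }
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
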
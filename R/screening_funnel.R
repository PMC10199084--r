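#' Consensus ranking configuration
#'
#' @param criteria data frame with columns `metric` (column name in the
#'   metric table), `direction` (`"lower"` or `"higher"` = better) and
#'   `weight` (>= 0, not all zero).
#' @param aggregation `"mean_rank"` (weights ignored, Borda-like) or
#'   `"weighted_mean_rank"`.
#' @return object of class `consensus_config`.
#' @export
consensus_config <- function(criteria = data.frame(metric = "binding_energy",
                                                   direction = "lower",
                                                   weight = 1),
                             aggregation = c("mean_rank", "weighted_mean_rank")) {
  aggregation <- match.arg(aggregation)
  stopifnot(nrow(criteria) >= 1,
            all(criteria$direction %in% c("lower", "higher")),
            all(criteria$weight >= 0), any(criteria$weight > 0))
  structure(list(criteria = criteria, aggregation = aggregation),
            class = "consensus_config")
}

#' Funnel configuration
#'
#' The default cutoffs implement a strict "lesser than -8.00 kcal/mol"
#' reading at both the virtual-screening and docking stages: a compound at
#' exactly -8.00 is eliminated, one at -8.10 survives.
#'
#' @param vs_cutoff virtual-screening binding-energy cutoff (kcal/mol, strict <).
#' @param dock_cutoff docking binding-energy cutoff (kcal/mol, strict <).
#' @param required_rules rule ids every survivor must pass.
#' @param metric_thresholds a [metric_thresholds()].
#' @param consensus a [consensus_config()].
#' @return object of class `funnel_config`.
#' @export
funnel_config <- function(vs_cutoff = -8.0, dock_cutoff = -8.0,
                          required_rules = c("lipinski", "pfizer"),
                          metric_thresholds = coxtriage::metric_thresholds(),
                          consensus = consensus_config()) {
  stopifnot(is.finite(vs_cutoff), is.finite(dock_cutoff))
  structure(list(vs_cutoff = vs_cutoff, dock_cutoff = dock_cutoff,
                 required_rules = required_rules,
                 metric_thresholds = metric_thresholds,
                 consensus = consensus),
            class = "funnel_config")
}

stage_result <- function(entering, survivors, eliminations) {
  list(entering = entering, surviving = survivors, eliminations = eliminations)
}

#' Binding-energy cutoff stage
#'
#' Survivors are exactly the entries with binding energy strictly below the
#' cutoff; every elimination records the observed energy and the cutoff.
#'
#' @param scores data frame with `compound_id` and `binding_energy` (kcal/mol).
#' @param cutoff cutoff in kcal/mol (strict `<`).
#' @return list with `survivors` (tibble) and `eliminations` (tibble with
#'   `compound_id`, `reason`).
#' @export
apply_energy_cutoff <- function(scores, cutoff = -8.0) {
  keep <- scores$binding_energy < cutoff
  eliminations <- tibble::tibble(
    compound_id = scores$compound_id[!keep],
    reason = sprintf("binding energy %.2f kcal/mol not < cutoff %.2f",
                     scores$binding_energy[!keep], cutoff)
  )
  list(survivors = tibble::as_tibble(scores[keep, , drop = FALSE]),
       eliminations = eliminations)
}

#' Drug-likeness rule stage
#'
#' A candidate survives iff every required rule reports "Accepted";
#' eliminations name the failed rules.
#'
#' @param candidates character vector of compound ids entering the stage.
#' @param outcomes tidy rule outcomes as from [screen_rules()] (`compound_id`,
#'   `rule_id`, `status`).
#' @param required_rules rule ids that must all be Accepted.
#' @return list with `survivors` (character) and `eliminations` (tibble).
#' @export
apply_rule_stage <- function(candidates, outcomes,
                             required_rules = c("lipinski", "pfizer")) {
  if (length(required_rules) == 0) {
    return(list(survivors = candidates,
                eliminations = tibble::tibble(compound_id = character(0),
                                              reason = character(0))))
  }
  survivors <- character(0)
  elim_id <- character(0)
  elim_reason <- character(0)
  for (id in candidates) {
    sub <- outcomes[outcomes$compound_id == id &
                      outcomes$rule_id %in% required_rules, ]
    missing_rules <- setdiff(required_rules, sub$rule_id)
    if (length(missing_rules) > 0) {
      stop(sprintf("candidate %s has no outcome for rule(s): %s", id,
                   paste(missing_rules, collapse = ", ")), call. = FALSE)
    }
    failed <- sub$rule_id[sub$status != "Accepted"]
    if (length(failed) == 0) {
      survivors <- c(survivors, id)
    } else {
      elim_id <- c(elim_id, id)
      elim_reason <- c(elim_reason,
                       sprintf("failed rule(s): %s", paste(failed, collapse = ", ")))
    }
  }
  list(survivors = survivors,
       eliminations = tibble::tibble(compound_id = elim_id, reason = elim_reason))
}

#' Ligand-efficiency metric stage
#'
#' A candidate survives iff all threshold flags in its efficiency report
#' pass; eliminations name the failed metrics with their values.
#'
#' @param candidates character vector of compound ids entering the stage.
#' @param reports output of [evaluate_metrics()] covering every candidate.
#' @param thresholds the [metric_thresholds()] used (for elimination
#'   messages).
#' @return list with `survivors` and `eliminations`.
#' @export
apply_metric_stage <- function(candidates, reports,
                               thresholds = metric_thresholds()) {
  survivors <- character(0)
  elim_id <- character(0)
  elim_reason <- character(0)
  flag_cols <- grep("^pass_(?!all)", names(reports), perl = TRUE, value = TRUE)
  metric_of <- c(pass_le = "le", pass_lle = "lle", pass_fq = "fq",
                 pass_lelp = "lelp", pass_ki = "ki")
  for (id in candidates) {
    row <- reports[reports$compound_id == id, ]
    if (nrow(row) != 1) {
      stop(sprintf("no efficiency report for candidate %s", id), call. = FALSE)
    }
    failed <- flag_cols[!unlist(row[flag_cols])]
    if (length(failed) == 0) {
      survivors <- c(survivors, id)
    } else {
      desc <- vapply(failed, function(fc) {
        metric <- metric_of[[fc]]
        if (metric == "lelp") {
          sprintf("LELP %.3f outside [%g, %g]", row$lelp,
                  thresholds$lelp_range[1], thresholds$lelp_range[2])
        } else {
          sprintf("%s %.3f below threshold", toupper(metric), row[[metric]])
        }
      }, character(1))
      elim_id <- c(elim_id, id)
      elim_reason <- c(elim_reason, paste(desc, collapse = "; "))
    }
  }
  list(survivors = survivors,
       eliminations = tibble::tibble(compound_id = elim_id, reason = elim_reason))
}

#' Direction-aware consensus ranking
#'
#' Ranks candidates on each criterion (ties share the mean rank), aggregates
#' the per-criterion ranks by (weighted) mean, and orders candidates by
#' ascending aggregate score with deterministic lexicographic tie-breaking on
#' the compound id. `final_rank` remains tie-aware (equal aggregates share
#' the mean final rank); the row order is the deterministic tie-broken one.
#'
#' @param metric_table data frame with `compound_id` and one column per
#'   criterion metric; every candidate needs a value for every weighted
#'   criterion.
#' @param config a [consensus_config()].
#' @return tibble: metric values, per-metric `rank_<metric>` columns,
#'   `aggregate`, `final_rank`.
#' @export
consensus_rank <- function(metric_table, config = consensus_config()) {
  stopifnot(inherits(config, "consensus_config"))
  crit <- config$criteria
  missing_cols <- setdiff(crit$metric, names(metric_table))
  if (length(missing_cols) > 0) {
    stop(sprintf("metric table missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  out <- tibble::as_tibble(metric_table)
  weights <- crit$weight
  if (config$aggregation == "mean_rank") weights <- rep(1, nrow(crit))
  rank_mat <- matrix(0, nrow(out), nrow(crit))
  for (i in seq_len(nrow(crit))) {
    x <- out[[crit$metric[i]]]
    if (any(is.na(x))) {
      stop(sprintf("missing values in metric '%s'", crit$metric[i]), call. = FALSE)
    }
    key <- if (crit$direction[i] == "lower") x else -x
    rank_mat[, i] <- rank(key, ties.method = "average")
    out[[paste0("rank_", crit$metric[i])]] <- rank_mat[, i]
  }
  out$aggregate <- as.numeric(rank_mat %*% weights) / sum(weights)
  ord <- order(out$aggregate, out$compound_id)
  out <- out[ord, ]
  out$final_rank <- rank(out$aggregate, ties.method = "average")
  out
}

#' Run the full screening funnel
#'
#' Executes the staged triage — docking-energy cutoff, drug-likeness rules,
#' ligand-efficiency metrics — records every elimination in a ledger, and
#' consensus-ranks the final survivors.
#'
#' @param scores data frame with `compound_id`, `binding_energy` (kcal/mol).
#' @param profiles data frame with `compound_id`, `mw`, `heavy_atoms`,
#'   `n_hba`, `n_hbd`, `tpsa`, `logp` (and optionally `ki_override`, molar)
#'   for every scored compound.
#' @param config a [funnel_config()].
#' @param thermo a [thermo_config()] for the Ki derivation.
#' @return list of class `screening_funnel_result` with `ledger` (class
#'   `screening_ledger`), `ranking` (tibble over the final survivors) and
#'   `survivors`.
#' @examples
#' tbl1 <- load_fixture("table1")
#' prof <- table3_profiles()
#' res <- run_funnel(tbl1, prof)
#' res$survivors
#' @export
run_funnel <- function(scores, profiles, config = funnel_config(),
                       thermo = thermo_config()) {
  stopifnot(inherits(config, "funnel_config"))
  orphans <- setdiff(scores$compound_id, profiles$compound_id)
  if (length(orphans) > 0) {
    stop(sprintf("no descriptor profile for compound(s): %s",
                 paste(orphans, collapse = ", ")), call. = FALSE)
  }
  ledger <- list()

  dock <- apply_energy_cutoff(scores, config$dock_cutoff)
  ledger$docking_cutoff <- stage_result(scores$compound_id,
                                        dock$survivors$compound_id,
                                        dock$eliminations)
  alive <- dock$survivors$compound_id

  if (length(config$required_rules) > 0 && length(alive) > 0) {
    outcomes <- screen_rules(profiles[profiles$compound_id %in% alive, ],
                             rules = config$required_rules)
  } else {
    outcomes <- tibble::tibble(compound_id = character(0), rule_id = character(0),
                               status = character(0))
  }
  rules <- apply_rule_stage(alive, outcomes, config$required_rules)
  ledger$rules <- stage_result(alive, rules$survivors, rules$eliminations)
  alive <- rules$survivors

  metric_inputs <- merge(scores[c("compound_id", "binding_energy")],
                         profiles, by = "compound_id")
  metric_inputs <- metric_inputs[metric_inputs$compound_id %in% alive, ]
  if (length(alive) > 0) {
    reports <- evaluate_metrics(metric_inputs, thermo, config$metric_thresholds)
  } else {
    reports <- evaluate_metrics(
      data.frame(compound_id = character(0), binding_energy = numeric(0),
                 heavy_atoms = numeric(0), logp = numeric(0)),
      thermo, config$metric_thresholds)
  }
  metrics <- apply_metric_stage(alive, reports, config$metric_thresholds)
  ledger$metrics <- stage_result(alive, metrics$survivors, metrics$eliminations)
  alive <- metrics$survivors

  rank_inputs <- merge(
    scores[scores$compound_id %in% alive, , drop = FALSE],
    reports[reports$compound_id %in% alive,
            setdiff(names(reports), "binding_energy"), drop = FALSE],
    by = "compound_id")
  ranking <- if (length(alive) > 0) {
    consensus_rank(rank_inputs, config$consensus)
  } else {
    tibble::tibble(compound_id = character(0), aggregate = numeric(0),
                   final_rank = numeric(0))
  }
  class(ledger) <- "screening_ledger"
  structure(list(ledger = ledger, ranking = ranking, survivors = alive),
            class = "screening_funnel_result")
}

#' @export
as.data.frame.screening_ledger <- function(x, ...) {
  do.call(rbind, lapply(names(x), function(stage) {
    s <- x[[stage]]
    data.frame(stage = stage, entering = length(s$entering),
               surviving = length(s$surviving),
               eliminated = nrow(s$eliminations))
  }))
}

#' @export
print.screening_ledger <- function(x, ...) {
  cat("Screening ledger:\n")
  print(as.data.frame(x))
  invisible(x)
}

#' @export
print.screening_funnel_result <- function(x, ...) {
  print(x$ledger)
  cat("\nFinal survivors:", paste(x$survivors, collapse = ", "), "\n")
  invisible(x)
}
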
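require_fields <- function(profile, fields, rule) {
  missing_f <- fields[!fields %in% names(profile) |
                        vapply(fields, function(f) is.null(profile[[f]]) ||
                                 all(is.na(profile[[f]])), logical(1))]
  if (length(missing_f) > 0) {
    stop(sprintf("%s rule requires field(s): %s", rule,
                 paste(missing_f, collapse = ", ")), call. = FALSE)
  }
}

#' Lipinski rule of five
#'
#' Counts violations of the four oral drug-likeness bounds (MW <= 500 Da,
#' logP <= 5, H-bond acceptors <= 10, H-bond donors <= 5); a compound is
#' Accepted with fewer than 2 violations.
#'
#' @param profile named list or one-row data frame with `mw`, `logp`,
#'   `n_hba`, `n_hbd`.
#' @return list with `rule_id`, `status` ("Accepted"/"Rejected") and a
#'   `violations` tibble (field, observed, bound).
#' @examples
#' lipinski_rule(list(mw = 180.04, logp = 1.237, n_hba = 4, n_hbd = 1))
#' @export
lipinski_rule <- function(profile) {
  require_fields(profile, c("mw", "logp", "n_hba", "n_hbd"), "Lipinski")
  bounds <- tibble::tibble(
    field = c("mw", "logp", "n_hba", "n_hbd"),
    observed = c(profile$mw, profile$logp, profile$n_hba, profile$n_hbd),
    bound = c(500, 5, 10, 5)
  )
  violations <- bounds[bounds$observed > bounds$bound, ]
  list(rule_id = "lipinski",
       status = if (nrow(violations) < 2) "Accepted" else "Rejected",
       violations = violations)
}

#' Pfizer (3/75) rule
#'
#' Compounds in the high-lipophilicity, low-polarity region (logP > 3 AND
#' TPSA < 75 A^2) carry an elevated in vivo toxicity risk and are Rejected;
#' everything else is Accepted. Both inequalities are strict, so a compound
#' at logP exactly 3 is Accepted.
#'
#' @param profile named list or one-row data frame with `logp` and `tpsa`.
#' @return list with `rule_id`, `status` and `violations` (the offending
#'   field/observed/bound rows when Rejected).
#' @examples
#' pfizer_rule(list(logp = 3.014, tpsa = 67.51)) # Rejected
#' @export
pfizer_rule <- function(profile) {
  require_fields(profile, c("logp", "tpsa"), "Pfizer")
  rejected <- profile$logp > 3 && profile$tpsa < 75
  violations <- if (rejected) {
    tibble::tibble(field = c("logp", "tpsa"),
                   observed = c(profile$logp, profile$tpsa),
                   bound = c(3, 75))
  } else {
    tibble::tibble(field = character(0), observed = numeric(0), bound = numeric(0))
  }
  list(rule_id = "pfizer",
       status = if (rejected) "Rejected" else "Accepted",
       violations = violations)
}

#' Parse a permissible-range declaration
#'
#' Small grammar for data-driven ADMET screening:
#' \itemize{
#'   \item one-sided bounds: `">x"`, `">=x"`, `"<x"`, `"<=x"` (strict or
#'     closed as written);
#'   \item closed intervals: `"a~b"`;
#'   \item ascending 3-band scales: `"band:b0;b1;b2;b3"` with labels
#'     excellent/medium/poor — only the first band is acceptable;
#'   \item descending 3-band scales: `"band_desc:t1;t2"` with labels
#'     high/moderate/low — only the first band (value > t1) is acceptable.
#' }
#' Values exactly on a closed bound are Accepted.
#'
#' @param spec a single range string.
#' @return list with `type`, a `classify(x)` function returning
#'   `list(accepted, band)`, and the original `spec`.
#' @export
parse_permissible_range <- function(spec) {
  spec0 <- gsub("[[:space:]]+", "", normalize_numeric_text(spec))
  num <- function(s) {
    v <- suppressWarnings(as.numeric(s))
    if (any(is.na(v))) stop(sprintf("unparseable range spec: '%s'", spec), call. = FALSE)
    v
  }
  if (grepl("^band:", spec0)) {
    b <- num(strsplit(sub("^band:", "", spec0), ";")[[1]])
    if (length(b) != 4) stop(sprintf("band spec needs 4 cut points: '%s'", spec), call. = FALSE)
    labels <- c("excellent", "medium", "poor")
    classify <- function(x) {
      band <- if (x <= b[2]) labels[1] else if (x <= b[3]) labels[2] else labels[3]
      list(accepted = x >= b[1] && x <= b[2], band = band)
    }
    type <- "band"
  } else if (grepl("^band_desc:", spec0)) {
    t <- num(strsplit(sub("^band_desc:", "", spec0), ";")[[1]])
    if (length(t) != 2) stop(sprintf("band_desc spec needs 2 cut points: '%s'", spec), call. = FALSE)
    labels <- c("high", "moderate", "low")
    classify <- function(x) {
      band <- if (x > t[1]) labels[1] else if (x >= t[2]) labels[2] else labels[3]
      list(accepted = x > t[1], band = band)
    }
    type <- "band_desc"
  } else if (grepl("^>=", spec0)) {
    v <- num(sub("^>=", "", spec0))
    classify <- function(x) list(accepted = x >= v, band = NA_character_)
    type <- "ge"
  } else if (grepl("^<=", spec0)) {
    v <- num(sub("^<=", "", spec0))
    classify <- function(x) list(accepted = x <= v, band = NA_character_)
    type <- "le"
  } else if (grepl("^>", spec0)) {
    v <- num(sub("^>", "", spec0))
    classify <- function(x) list(accepted = x > v, band = NA_character_)
    type <- "gt"
  } else if (grepl("^<", spec0)) {
    v <- num(sub("^<", "", spec0))
    classify <- function(x) list(accepted = x < v, band = NA_character_)
    type <- "lt"
  } else if (grepl("~", spec0, fixed = TRUE)) {
    ab <- num(strsplit(spec0, "~", fixed = TRUE)[[1]])
    if (length(ab) != 2) stop(sprintf("unparseable range spec: '%s'", spec), call. = FALSE)
    classify <- function(x) list(accepted = x >= ab[1] && x <= ab[2],
                                 band = NA_character_)
    type <- "interval"
  } else {
    stop(sprintf("unparseable range spec: '%s'", spec), call. = FALSE)
  }
  list(type = type, classify = classify, spec = spec)
}

#' Screen descriptor values against declared permissible ranges
#'
#' One outcome per field: Accepted iff the value lies within its permissible
#' range (for 3-band scales, iff it falls in the first band; the band label
#' is reported either way).
#'
#' @param values named numeric vector (or named list) of observed values.
#' @param ranges named character vector of range declarations in the grammar
#'   of [parse_permissible_range()]; defaults to the ranges attached to
#'   [table3_profiles()]. Fields without a declared range are skipped.
#' @return tibble with `field`, `value`, `range`, `band`, `status`.
#' @examples
#' range_screen(c(`Caco-2 Permeability` = -5.598, PPB = 0.99),
#'              c(`Caco-2 Permeability` = ">-5.15", PPB = "<=0.90"))
#' @export
range_screen <- function(values, ranges = attr(table3_profiles(), "ranges")) {
  values <- unlist(values)
  fields <- intersect(names(values), names(ranges))
  rows <- lapply(fields, function(f) {
    if (is.na(values[[f]])) return(NULL)
    r <- parse_permissible_range(ranges[[f]])
    cls <- r$classify(values[[f]])
    tibble::tibble(field = f, value = values[[f]], range = ranges[[f]],
                   band = cls$band,
                   status = if (cls$accepted) "Accepted" else "Rejected")
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- tibble::tibble(field = character(0), value = numeric(0),
                          range = character(0), band = character(0),
                          status = character(0))
  }
  out
}

#' Apply the named drug-likeness rules to a table of profiles
#'
#' Convenience wrapper used by the screening funnel: runs [lipinski_rule()]
#' and/or [pfizer_rule()] over every row of a profile table.
#'
#' @param profiles data frame with `compound_id` plus the fields each rule
#'   needs (`mw`, `logp`, `n_hba`, `n_hbd`, `tpsa`).
#' @param rules character vector among `"lipinski"`, `"pfizer"`.
#' @return tidy tibble with `compound_id`, `rule_id`, `status`,
#'   `n_violations`.
#' @export
screen_rules <- function(profiles, rules = c("lipinski", "pfizer")) {
  rules <- match.arg(rules, several.ok = TRUE)
  engines <- list(lipinski = lipinski_rule, pfizer = pfizer_rule)
  out <- lapply(seq_len(nrow(profiles)), function(i) {
    profile <- as.list(profiles[i, ])
    do.call(rbind, lapply(rules, function(r) {
      res <- engines[[r]](profile)
      tibble::tibble(compound_id = profile$compound_id, rule_id = res$rule_id,
                     status = res$status, n_violations = nrow(res$violations))
    }))
  })
  do.call(rbind, out)
}
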
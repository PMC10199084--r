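#' Normalise numeric text transcribed from typeset tables
#'
#' Replaces the Unicode minus sign (U+2212) with the ASCII hyphen-minus and
#' strips internal whitespace, so values such as \code{"− 9.35"} parse as
#' \code{-9.35}. Parsing is locale-independent: only \code{"."} is accepted as
#' the decimal mark.
#'
#' @param x character vector.
#' @return character vector ready for [as.numeric()].
#' @keywords internal
normalize_numeric_text <- function(x) {
  x <- gsub("−", "-", x, fixed = TRUE)
  gsub("[[:space:]]+", "", x)
}

# parse a character column to numeric; blank/NA cells stay NA, anything else
# that fails to parse raises a row-indexed error
parse_numeric_column <- function(x, column, allow_na = FALSE) {
  raw <- as.character(x)
  out <- suppressWarnings(as.numeric(normalize_numeric_text(raw)))
  blank <- is.na(raw) | trimws(raw) == ""
  bad <- which(is.na(out) & !blank)
  if (length(bad) > 0) {
    stop(sprintf(
      "cannot parse %s in column '%s' at row %s",
      paste(sQuote(raw[bad[1]]), collapse = ", "), column, bad[1]
    ), call. = FALSE)
  }
  if (!allow_na && any(blank)) {
    stop(sprintf("missing value in column '%s' at row %d", column, which(blank)[1]),
         call. = FALSE)
  }
  out
}

#' Read a compound score table from CSV
#'
#' Reads a comma-separated table of screened compounds and joins the identity
#' and score columns into one record per row. Column names in the file are
#' mapped onto canonical field names through `schema`; unmapped columns are
#' preserved untouched so ADMET-style tables with many extra fields pass
#' through intact.
#'
#' @param path path to a CSV file with a header row.
#' @param schema named character vector mapping canonical field names to
#'   column names in the file, e.g.
#'   `c(compound_id = "compound_id", binding_energy = "binding_energy")`.
#' @param numeric_fields canonical field names to parse as numeric (both the
#'   ASCII and Unicode minus sign are accepted). Defaults to
#'   `"binding_energy"` when that field is mapped.
#' @return a [tibble::tibble] with the canonical columns first (file row order
#'   preserved), followed by any extra columns.
#' @examples
#' path <- system.file("extdata", "table1.csv", package = "coxtriage")
#' read_compound_table(path)
#' @export
read_compound_table <- function(path,
                                schema = c(compound_id = "compound_id",
                                           binding_energy = "binding_energy"),
                                numeric_fields = intersect("binding_energy",
                                                           names(schema))) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(schema), names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("column(s) missing from %s: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  canon <- raw[, unname(schema), drop = FALSE]
  names(canon) <- names(schema)
  extra <- raw[, setdiff(names(raw), unname(schema)), drop = FALSE]
  out <- cbind(canon, extra)
  for (field in numeric_fields) {
    out[[field]] <- parse_numeric_column(out[[field]], field)
  }
  if ("compound_id" %in% names(out)) {
    if (any(!nzchar(out$compound_id))) {
      stop("compound_id must be non-empty", call. = FALSE)
    }
    if (anyDuplicated(out$compound_id) > 0) {
      stop(sprintf("duplicate compound_id: %s",
                   out$compound_id[duplicated(out$compound_id)][1]), call. = FALSE)
    }
  }
  tibble::as_tibble(out)
}

#' Parse a docking engine result log
#'
#' Extracts one binding energy per ligand from a plain-text docking log.
#' For the `vina` dialect the affinity of binding mode 1 (the top-ranked pose)
#' is taken from each result table; for the `autodock4` dialect the lowest
#' free binding energy over the clustering histogram is taken, matching the
#' convention of selecting the conformer with the lowest free binding energy.
#'
#' @param path path to the log file.
#' @param dialect `"vina"` or `"autodock4"`.
#' @return tibble with `compound_id`, `binding_energy` (kcal/mol) and `source`.
#' @export
parse_docking_log <- function(path, dialect = c("vina", "autodock4")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "vina") {
    ligand_at <- grep("^Ligand:", lines)
    sep_at <- grep("^-{4,}\\+", lines)
    if (length(sep_at) == 0) {
      stop("no result block found in vina log", call. = FALSE)
    }
    if (length(sep_at) > 1 && length(ligand_at) < length(sep_at)) {
      stop("multiple result blocks without ligand ids: ambiguous vina log",
           call. = FALSE)
    }
    ids <- character(0)
    energies <- numeric(0)
    for (k in seq_along(sep_at)) {
      mode1 <- NULL
      for (i in seq(sep_at[k] + 1, length(lines))) {
        fields <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
        if (length(fields) >= 2 && fields[1] == "1") {
          mode1 <- suppressWarnings(as.numeric(normalize_numeric_text(fields[2])))
          break
        }
        if (!grepl("^[[:space:]]*[0-9]", lines[i])) break
      }
      if (is.null(mode1) || is.na(mode1)) {
        stop("no mode-1 affinity found in vina result block", call. = FALSE)
      }
      prior <- ligand_at[ligand_at < sep_at[k]]
      id <- if (length(prior) > 0) {
        trimws(sub("^Ligand:", "", lines[max(prior)]))
      } else {
        tools::file_path_sans_ext(basename(path))
      }
      ids <- c(ids, id)
      energies <- c(energies, mode1)
    }
  } else {
    # autodock4 clustering histogram rows look like
    #   "   1 |     -9.35 | ..." (rank | lowest binding energy | ...)
    hist_rows <- grep("^[[:space:]]*[0-9]+[[:space:]]*\\|", lines, value = TRUE)
    if (length(hist_rows) == 0) {
      stop("no clustering histogram found in autodock4 log", call. = FALSE)
    }
    energy <- vapply(hist_rows, function(row) {
      fields <- strsplit(row, "\\|")[[1]]
      suppressWarnings(as.numeric(normalize_numeric_text(fields[2])))
    }, numeric(1), USE.NAMES = FALSE)
    if (all(is.na(energy))) {
      stop("no parseable binding energies in autodock4 histogram", call. = FALSE)
    }
    lig_at <- grep("^Ligand file:", lines, value = TRUE)
    ids <- if (length(lig_at) == 1) {
      tools::file_path_sans_ext(basename(trimws(sub("^Ligand file:", "", lig_at))))
    } else if (length(lig_at) > 1) {
      stop("multiple ligands in one autodock4 log: ambiguous", call. = FALSE)
    } else {
      tools::file_path_sans_ext(basename(path))
    }
    energies <- min(energy, na.rm = TRUE)
  }
  tibble::tibble(compound_id = ids, binding_energy = energies, source = dialect)
}

#' Load a shipped reference table
#'
#' The four reference tables of the source study are shipped verbatim as CSV
#' fixtures: `table1` (docking binding energies of the screened analogs,
#' parent compound and controls, kcal/mol), `table3` (physicochemical and
#' ADMET descriptors with their permissible ranges), `table4` (ligand
#' efficiency metrics as printed) and `table5` (HOMO/LUMO/HLG in eV and
#' electrostatic potential energies of compound, peptide and adduct in
#' kcal/mol).
#'
#' @param name one of `"table1"`, `"table3"`, `"table4"`, `"table5"`.
#' @return a tibble holding the printed values.
#' @examples
#' load_fixture("table4")
#' @export
load_fixture <- function(name) {
  allowed <- c("table1", "table3", "table4", "table5")
  if (length(name) != 1 || !name %in% allowed) {
    stop(sprintf("unknown fixture '%s'; expected one of %s",
                 paste(name, collapse = ","), paste(allowed, collapse = ", ")),
         call. = FALSE)
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "coxtriage")
  if (!nzchar(path)) stop(sprintf("fixture file for '%s' not installed", name))
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         stringsAsFactors = FALSE)
  numeric_cols <- switch(
    name,
    table1 = "binding_energy",
    table3 = character(0), # mixed rows (Accepted/Rejected cells stay character)
    table4 = c("ki_uM", "le", "lle", "le_scale", "fq", "lelp"),
    table5 = c("homo_eV", "lumo_eV", "hlg_eV",
               "epe_compound", "epe_adduct", "be_adduct")
  )
  for (col in numeric_cols) {
    raw[[col]] <- parse_numeric_column(raw[[col]], col, allow_na = TRUE)
  }
  tibble::as_tibble(raw)
}

#' Per-compound descriptor profiles from the shipped ADMET table
#'
#' Pivots the descriptor fixture (parameters as rows, compounds as columns)
#' into one numeric profile per compound with canonical names for the fields
#' the rule engines consume (`mw`, `heavy_atoms`, `n_hba`, `n_hbd`, `tpsa`,
#' `logp`). All other numeric parameters are carried as extra columns; the
#' declared permissible ranges are attached as the `"ranges"` attribute
#' (named character vector in the range grammar of [range_screen()]).
#'
#' @param tbl a table in the layout of `load_fixture("table3")`.
#' @return tibble with one row per compound; attribute `"ranges"`.
#' @export
table3_profiles <- function(tbl = load_fixture("table3")) {
  canonical <- c(MW = "mw", HA = "heavy_atoms", nHA = "n_hba", nHD = "n_hbd",
                 TPSA = "tpsa", logP = "logp")
  compound_cols <- setdiff(names(tbl), c("category", "parameter", "permissible_range"))
  numeric_rows <- !(tbl$parameter %in% c("Lipinski Rule", "Pfizer Rule"))
  params <- tbl$parameter[numeric_rows]
  mat <- vapply(compound_cols, function(cc) {
    parse_numeric_column(tbl[[cc]][numeric_rows], cc, allow_na = TRUE)
  }, numeric(sum(numeric_rows)))
  profiles <- tibble::as_tibble(t(mat), .name_repair = "minimal")
  names(profiles) <- ifelse(params %in% names(canonical),
                            canonical[params], params)
  profiles <- tibble::add_column(profiles, compound_id = compound_cols,
                                 .before = 1)
  ranges <- tbl$permissible_range[numeric_rows]
  names(ranges) <- names(profiles)[-1]
  attr(profiles, "ranges") <- ranges[nzchar(ranges)]
  profiles
}

#' Write a report table to CSV
#'
#' Writes a homogeneous set of report rows with a deterministic column order
#' so that a round-trip read returns the written values to full precision.
#'
#' @param rows a data frame, or a list of named lists sharing one field set.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_report_table <- function(rows, path) {
  if (!is.data.frame(rows)) {
    if (!is.list(rows)) stop("rows must be a data frame or list of named lists")
    if (length(rows) > 0) {
      fields <- lapply(rows, names)
      if (!all(vapply(fields, identical, logical(1), fields[[1]]))) {
        stop("heterogeneous rows: all rows must share one field set", call. = FALSE)
      }
      rows <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
    } else {
      rows <- data.frame()
    }
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) stop(sprintf("unwritable path: %s", path), call. = FALSE)
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
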
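#' Load a fermentation condition/phenotype table
#'
#' Reads a tab-delimited fermentation study table: one row per fermentor with
#' the five condition factors (NaCl mM, amino-acid factor, temperature,
#' pH, aeration gas), the growth phenotypes (`od_max`, `mu_max`) and
#' optionally endpoint organic-acid concentrations (mM), batch `day`,
#' `replicate_group` and a `transcriptome` flag marking fermentors from which
#' in-growth transcriptome samples were taken.
#'
#' @param path Path to a TSV file (UTF-8, "." decimal separator).
#' @param strict If `TRUE` (default) condition values must belong to the
#'   declared level sets (0/300 mM NaCl, 1.1/2.0x amino acids, 28/37 degC,
#'   pH 5.2/5.8/6.4, N2/O2 sparging); values are compared as exact printed
#'   codes, not floating tolerances.
#' @return A tibble of class `ferm_table`, one row per fermentor in file
#'   order, with a `factor_levels` attribute.
#' @export
#' @examples
#' tab <- load_fermentation_table(ferm_example("table1_fermentations.tsv"))
#' nrow(tab)
load_fermentation_table <- function(path, strict = TRUE) {
  if (!file.exists(path)) abort_ferm(paste0("file not found: ", path), "format")
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("ferm_id", ferm_condition_cols, "od_max", "mu_max")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort_ferm(paste0("missing required column(s): ", paste(missing, collapse = ", ")),
               "format")
  }
  if (nrow(raw) == 0) abort_ferm("empty table: file has a header but no records", "validation")
  dup <- raw$ferm_id[duplicated(raw$ferm_id)]
  if (length(dup)) {
    abort_ferm(paste0("duplicate ferm_id: ", paste(unique(dup), collapse = ", ")),
               "validation")
  }

  parse_num <- function(col) {
    x <- raw[[col]]
    out <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & nzchar(trimws(x)) & is.na(out)
    if (any(bad)) {
      abort_ferm(paste0("non-numeric value in column '", col, "' for fermentor ",
                        raw$ferm_id[which(bad)[1]]), "parse")
    }
    out
  }

  num_cols <- intersect(c(setdiff(ferm_condition_cols, "aeration"),
                          "od_max", "mu_max", ferm_acid_cols), names(raw))
  tab <- tibble(ferm_id = raw$ferm_id)
  for (col in num_cols) tab[[col]] <- parse_num(col)
  tab$aeration <- toupper(trimws(raw$aeration))
  if ("day" %in% names(raw)) tab$day <- as.integer(parse_num("day"))
  if ("replicate_group" %in% names(raw)) {
    rg <- trimws(raw$replicate_group)
    tab$replicate_group <- ifelse(is.na(rg) | !nzchar(rg), NA_character_, rg)
  }
  if ("transcriptome" %in% names(raw)) {
    tr <- toupper(trimws(raw$transcriptome))
    ok <- is.na(tr) | tr %in% c("0", "1", "TRUE", "FALSE")
    if (!all(ok)) {
      abort_ferm(paste0("transcriptome flag must be 0/1 or TRUE/FALSE (fermentor ",
                        raw$ferm_id[which(!ok)[1]], ")"), "parse")
    }
    tab$transcriptome <- tr %in% c("1", "TRUE")
  }

  bad_aer <- !tab$aeration %in% c("N2", "O2")
  if (any(bad_aer)) {
    abort_ferm(paste0("aeration must be N2 or O2 (fermentor ",
                      tab$ferm_id[which(bad_aer)[1]], ")"), "validation")
  }
  for (col in c("od_max", "mu_max")) {
    bad <- !is.na(tab[[col]]) & tab[[col]] <= 0
    if (any(bad)) {
      abort_ferm(paste0(col, " must be positive (fermentor ",
                        tab$ferm_id[which(bad)[1]], ")"), "validation")
    }
  }
  levels <- default_factor_levels()
  if (strict) {
    for (f in ferm_condition_cols) {
      bad <- !is.na(tab[[f]]) & !tab[[f]] %in% levels[[f]]
      if (any(bad)) {
        abort_ferm(paste0("condition '", f, "' outside declared levels (fermentor ",
                          tab$ferm_id[which(bad)[1]], "); use strict = FALSE to allow"),
                   "validation")
      }
    }
  } else {
    for (f in ferm_condition_cols) {
      levels[[f]] <- sort(unique(c(levels[[f]], tab[[f]][!is.na(tab[[f]])])))
    }
  }
  tab <- tab[, c("ferm_id", ferm_condition_cols,
                 intersect(c("od_max", "mu_max", ferm_acid_cols, "day",
                             "replicate_group", "transcriptome"), names(tab)))]
  new_ferm_table(tab, levels)
}

new_ferm_table <- function(tab, factor_levels = default_factor_levels()) {
  attr(tab, "factor_levels") <- factor_levels
  class(tab) <- unique(c("ferm_table", class(tab)))
  tab
}

#' @param table A `ferm_table` tibble.
#' @rdname load_fermentation_table
#' @export
write_fermentation_table <- function(table, path) {
  readr::write_tsv(as_tibble(table), path, progress = FALSE)
  invisible(path)
}

#' The packaged 30-fermentor study table
#'
#' Loads the packaged fermentation table of the 30-fermentor *Lactobacillus
#' plantarum* WCFS1 study: a balanced fractional factorial design over five
#' condition factors (24 distinct conditions plus replicated controls) with
#' the recorded ODmax and maximum specific growth rate of every fermentor.
#'
#' @return A `ferm_table` with 30 records.
#' @export
table1_fermentations <- function() {
  load_fermentation_table(ferm_example("table1_fermentations.tsv"))
}

#' Count distinct fermentation conditions
#'
#' Groups the fermentors of a study table by their exact condition tuple
#' (NaCl, amino-acid factor, temperature, pH, aeration). Replicated control
#' fermentations collapse onto the same design point, so the distinct count
#' is the number of design points actually realized.
#'
#' @param table A `ferm_table`.
#' @return A list with `n_conditions` (integer) and `groups`, a tibble of one
#'   row per distinct condition tuple (in first-appearance order) with the
#'   member `ferm_ids` as a list-column; group sizes always sum to the number
#'   of records.
#' @export
distinct_conditions <- function(table) {
  stopifnot(nrow(table) > 0)
  key <- do.call(paste, c(lapply(ferm_condition_cols, function(f) table[[f]]),
                          sep = "\r"))
  first <- !duplicated(key)
  groups <- as_tibble(table)[first, ferm_condition_cols]
  groups$ferm_ids <- lapply(key[first], function(k) table$ferm_id[key == k])
  groups$n <- lengths(groups$ferm_ids)
  list(n_conditions = sum(first), groups = groups)
}

#' Range of a phenotype over a study table
#'
#' @param table A `ferm_table`.
#' @param phenotype Name of a phenotype column (e.g. `"mu_max"`).
#' @return One-row tibble with `min`, `max` and the fermentor ids attaining
#'   them (`argmin`, `argmax`); ties resolve to the first record in table
#'   order, records with a missing value are ignored.
#' @export
phenotype_range <- function(table, phenotype) {
  if (!phenotype %in% names(table)) {
    abort_ferm(paste0("unknown phenotype '", phenotype, "'"), "key")
  }
  v <- table[[phenotype]]
  keep <- !is.na(v)
  if (!any(keep)) abort_ferm(paste0("phenotype '", phenotype, "' has no values"), "key")
  v <- v[keep]
  ids <- table$ferm_id[keep]
  tibble(phenotype = phenotype,
         min = min(v), max = max(v),
         argmin = ids[which.min(v)], argmax = ids[which.max(v)])
}

#' Check factorial-design balance
#'
#' Reports, for every condition factor, how many *distinct design points*
#' carry each level, and flags every two-factor level combination realized by
#' zero design points (a combination whose interaction the design cannot
#' see). A balanced fractional factorial shows equal per-level counts for the
#' two-level factors.
#'
#' @param table A `ferm_table`.
#' @return A `balance_report` list: `n_design_points`, `levels` (tibble:
#'   factor, level, n_design_points) and `missing_pairs` (tibble of absent
#'   two-factor combinations, zero rows when none).
#' @export
validate_design <- function(table) {
  dc <- distinct_conditions(table)
  dd <- dc$groups
  levels <- attr(table, "factor_levels") %||% default_factor_levels()

  lev_rows <- purrr::map_dfr(ferm_condition_cols, function(f) {
    lv <- levels[[f]] %||% sort(unique(dd[[f]]))
    tibble(factor = f, level = as.character(lv),
           n_design_points = vapply(lv, function(l) sum(dd[[f]] == l),
                                    integer(1), USE.NAMES = FALSE))
  })

  pairs <- utils::combn(ferm_condition_cols, 2, simplify = FALSE)
  missing <- purrr::map_dfr(pairs, function(p) {
    grid <- expand.grid(l1 = levels[[p[1]]], l2 = levels[[p[2]]],
                        stringsAsFactors = FALSE)
    hit <- mapply(function(a, b) any(dd[[p[1]]] == a & dd[[p[2]]] == b),
                  grid$l1, grid$l2)
    if (all(hit)) return(tibble())
    tibble(factor1 = p[1], level1 = as.character(grid$l1[!hit]),
           factor2 = p[2], level2 = as.character(grid$l2[!hit]))
  })
  if (nrow(missing)) {
    warn(paste0("design has ", nrow(missing),
                " two-factor level combination(s) with zero design points, e.g. (",
                missing$factor1[1], "=", missing$level1[1], ", ",
                missing$factor2[1], "=", missing$level2[1], ")"))
  }
  structure(list(n_design_points = dc$n_conditions,
                 levels = lev_rows, missing_pairs = missing),
            class = "balance_report")
}

#' Serialize a balance report to JSON
#'
#' @param report A `balance_report` from [validate_design()].
#' @param path Output path.
#' @export
write_balance_report <- function(report, path) {
  jsonlite::write_json(
    list(n_design_points = report$n_design_points,
         levels = report$levels, missing_pairs = report$missing_pairs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.balance_report <- function(x, ...) {
  cat("Factorial balance over", x$n_design_points, "distinct design points\n")
  print(x$levels)
  if (nrow(x$missing_pairs)) {
    cat("Missing two-factor combinations:\n"); print(x$missing_pairs)
  } else cat("All two-factor level combinations are realized.\n")
  invisible(x)
}
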
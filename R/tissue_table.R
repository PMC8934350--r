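#' Read a tissue parameter table
#'
#' Parses a delimited table of per-tissue model parameters: the geometry of
#' the normal and tumor clouds along PC1, the fluctuation scale, stem-cell
#' counts and turnover rates, and observed lifetime risks. Mandatory columns
#' are `tissue`, `xbar1`, `rn`, `rt`, `d_scale`; the optional columns
#' `r_walk`, `n_sc`, `m_sc`, `risk`, `dev` may be absent entirely or left
#' empty (an empty cell or a `"."` marks a missing value — missing entries are
#' stored as `NA`, never coerced to 0).
#'
#' Column names map onto the usual model symbols: `xbar1` is the tumor-cloud
#' center along PC1 (x-bar-1), `rn` and `rt` the r.m.s. radii of the normal
#' and tumor clouds (R_n, R_t), `r_walk` the minimal walk length R between
#' the cloud edges, `d_scale` the per-generation fluctuation scale D,
#' `n_sc` the tissue stem-cell count N_sc, `m_sc` the stem-cell turnover
#' rate (1/year), and `risk`/`dev` the mean and standard deviation of the
#' lifetime risk, stored as probabilities in (0, 1).
#'
#' Validation enforces: positive `xbar1`, `rn`, `rt`, `d_scale`; unique
#' tissue labels; `risk` in (0, 1), `n_sc >= 1`, `m_sc > 0` where present;
#' and, where `r_walk` is present, consistency with the derived value
#' `xbar1 - rn - rt` to within 0.01.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A `tissue_table`: a tibble with one row per tissue and a
#'   `provenance` attribute carrying a free-text source note.
#' @seealso [tissue_parameters()] for the packaged table,
#'   [complete_rows()], [write_tissue_table()]
#' @export
read_tissue_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("tissue table file not found: ", path)
  }
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- read.delim(path, sep = sep, colClasses = "character",
                    check.names = TRUE, strip.white = TRUE)
  mandatory <- c("tissue", "xbar1", "rn", "rt", "d_scale")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    stop("tissue table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  optional <- c("r_walk", "n_sc", "m_sc", "risk", "dev")
  for (col in setdiff(optional, names(raw))) raw[[col]] <- NA_character_
  raw <- raw[c("tissue", "xbar1", "rn", "rt", "r_walk", "d_scale", optional[-1])]

  numeric_cols <- setdiff(names(raw), "tissue")
  parsed <- raw
  for (col in numeric_cols) {
    parsed[[col]] <- parse_table_numeric(raw[[col]], col)
  }
  tab <- as_tibble(parsed)
  tab$tissue <- trimws(tab$tissue)

  new_tissue_table(tab, provenance = path)
}

# "" and "." mark absent values; anything else must parse as a number
parse_table_numeric <- function(x, col) {
  x <- trimws(x)
  absent <- is.na(x) | x == "" | x == "." | x == "...."
  out <- rep(NA_real_, length(x))
  if (any(!absent)) {
    val <- suppressWarnings(as.numeric(x[!absent]))
    if (anyNA(val)) {
      bad <- which(!absent)[which(is.na(val))]
      stop("column '", col, "' has non-numeric value(s) in row(s): ",
           paste(bad, collapse = ", "))
    }
    out[!absent] <- val
  }
  out
}

new_tissue_table <- function(tab, provenance = "") {
  validate_tissue_table(tab)
  structure(tab,
            provenance = provenance,
            class = c("tissue_table", class(tibble())))
}

validate_tissue_table <- function(tab) {
  if (nrow(tab) == 0) return(invisible(tab))
  if (anyDuplicated(tab$tissue)) {
    dup <- unique(tab$tissue[duplicated(tab$tissue)])
    stop("duplicate tissue label(s): ", paste(dup, collapse = ", "))
  }
  check_pos <- function(col) {
    bad <- which(is.na(tab[[col]]) | tab[[col]] <= 0)
    if (length(bad) > 0) {
      stop("column '", col, "' must be present and > 0; offending row(s): ",
           paste(bad, collapse = ", "))
    }
  }
  for (col in c("xbar1", "rn", "rt", "d_scale")) check_pos(col)

  has_r <- !is.na(tab$r_walk)
  if (any(has_r)) {
    derived <- tab$xbar1 - tab$rn - tab$rt
    off <- which(has_r & abs(tab$r_walk - derived) > 0.01 + 1e-9)
    if (length(off) > 0) {
      stop("r_walk inconsistent with xbar1 - rn - rt (tolerance 0.01) in ",
           "row(s): ", paste(off, collapse = ", "))
    }
  }
  bad_risk <- which(!is.na(tab$risk) & (tab$risk <= 0 | tab$risk >= 1))
  if (length(bad_risk) > 0) {
    stop("risk must lie in (0, 1); offending row(s): ",
         paste(bad_risk, collapse = ", "))
  }
  bad_nsc <- which(!is.na(tab$n_sc) & tab$n_sc < 1)
  if (length(bad_nsc) > 0) {
    stop("n_sc must be >= 1; offending row(s): ",
         paste(bad_nsc, collapse = ", "))
  }
  bad_msc <- which(!is.na(tab$m_sc) & tab$m_sc <= 0)
  if (length(bad_msc) > 0) {
    stop("m_sc must be > 0; offending row(s): ",
         paste(bad_msc, collapse = ", "))
  }
  invisible(tab)
}

#' Write a tissue parameter table
#'
#' Inverse of [read_tissue_table()]: numeric fields are written at full
#' precision (round-trips exactly through `read_tissue_table()`), missing
#' values as empty cells.
#'
#' @param table A `tissue_table`.
#' @param path Output path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_tissue_table <- function(table, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  out <- as.data.frame(table)
  for (col in setdiff(names(out), "tissue")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         format(out[[col]], digits = 17, trim = TRUE,
                                scientific = FALSE))
  }
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Packaged tissue parameter table
#'
#' Returns the compiled table of model parameters for 15 TCGA cancer types:
#' PC1 geometry (`xbar1`, `rn`, `rt`, the derived minimal walk length
#' `r_walk`, fluctuation scale `d_scale`) for all 15, plus stem-cell counts,
#' turnover rates and registry lifetime risks for the 8 tissues where all are
#' available (BRCA, COAD, ESCA, HNSC, LIHC, LUAD, PRAD, THCA). These 8
#' complete rows are the inputs of the Brownian and Levy regression tests;
#' see [fit_risk_model()].
#'
#' @return A `tissue_table` with 15 rows.
#' @examples
#' tab <- tissue_parameters()
#' complete_rows(tab)$tissue
#' @export
tissue_parameters <- function() {
  path <- system.file("extdata", "table2_tissues.tsv", package = "levyrisk",
                      mustWork = TRUE)
  tab <- read_tissue_table(path)
  attr(tab, "provenance") <- "packaged 15-tissue parameter compilation"
  tab
}

#' Subset a tissue table to rows with complete model data
#'
#' Keeps the rows for which the stem-cell count `n_sc`, turnover rate `m_sc`
#' and lifetime `risk` are all present — the rows usable in the risk
#' regressions. Order is preserved.
#'
#' @param table A `tissue_table`.
#' @return A `tissue_table` containing the complete rows only.
#' @export
complete_rows <- function(table) {
  keep <- !is.na(table$n_sc) & !is.na(table$m_sc) & !is.na(table$risk)
  out <- table[keep, , drop = FALSE]
  new_tissue_table(as_tibble(out), provenance = attr(table, "provenance"))
}

#' @export
print.tissue_table <- function(x, ...) {
  cat("<tissue_table> ", nrow(x), " tissues (",
      sum(!is.na(x$n_sc) & !is.na(x$m_sc) & !is.na(x$risk)),
      " with complete risk data)\n", sep = "")
  prov <- attr(x, "provenance")
  if (!is.null(prov) && nzchar(prov)) cat("provenance: ", prov, "\n", sep = "")
  NextMethod()
}
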
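#' Names of the thirteen measured responses
#'
#' The quality responses recorded for every run of the dehydration
#' experiment: the three process indices (DMC, WL, SG), four minerals,
#' two radical-scavenging IC50 values, flavonoid and phenol content,
#' titratable acidity and betaine content.
#'
#' @return Character vector of length 13.
#' @export
od_response_names <- function() {
  c("DMC", "WL", "SG", "Mg", "K", "Na", "Ca",
    "DPPH", "ABTS", "flavonoids", "phenols", "acidity", "betaine")
}

#' Names of the three process factors
#'
#' @return Character vector: temperature `T` (degrees C), osmotic-solution
#'   concentration `Conc` (% mass) and process time `t` (h).
#' @export
od_factor_names <- function() c("T", "Conc", "t")

#' Measurement units for factors and responses
#'
#' @return Named character vector mapping each column name to its unit
#'   string. Mineral contents are recorded as "mg/kg", the unit printed
#'   in the source run table's header.
#' @export
od_units <- function() {
  c(T = "degC", Conc = "% mass", t = "h",
    DMC = "%", WL = "g/g f.s.", SG = "g/g f.s.",
    Mg = "mg/kg", K = "mg/kg", Na = "mg/kg", Ca = "mg/kg",
    DPPH = "IC50 (mg/mL)", ABTS = "IC50 (mg/mL)",
    flavonoids = "mg ECA/100 g d.m.", phenols = "mg eq.GA/100 g d.m.",
    acidity = "% d.m.", betaine = "mg/100 g d.m.")
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "osmodry")
  if (!nzchar(path)) stop("packaged fixture not found: ", file)
  path
}

# Parse character columns to numeric, reporting the first offending cell.
.numeric_columns <- function(raw, cols, what) {
  for (col in cols) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]) & nzchar(trimws(raw[[col]])))
    if (length(bad) > 0L) {
      stop(sprintf("%s: non-numeric value '%s' in row %d, column '%s'",
                   what, raw[[col]][bad[1L]], bad[1L], col))
    }
    raw[[col]] <- vals
  }
  raw
}

#' Load a dehydration design table
#'
#' Reads a run table of a 3-factor Box-Behnken dehydration experiment:
#' one row per run, columns `run`, `T`, `Conc`, `t` and the 13 responses
#' (see [od_response_names()]), optionally accompanied by `<name>_sd`
#' standard-deviation columns. The builtin name `"table1"` loads the
#' packaged 15-run beetroot-in-molasses experiment.
#'
#' @param source path to a CSV file (comma separated, period decimal mark),
#'   or the builtin name `"table1"`.
#' @return A `data.frame` of class `"od_design"` with a `units` attribute.
#' @examples
#' d <- load_design_table("table1")
#' d$DMC[d$run == 8]
#' @export
load_design_table <- function(source = "table1") {
  path <- if (identical(source, "table1")) .extdata("table1.csv") else source
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  required <- c("run", od_factor_names(), od_response_names())
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("design table is missing column(s): ", paste(missing, collapse = ", "))
  }
  sd_cols <- intersect(paste0(od_response_names(), "_sd"), names(raw))
  raw <- .numeric_columns(raw, c(required, sd_cols), "design table")
  if (anyDuplicated(raw$run)) {
    stop("duplicate run id(s): ",
         paste(unique(raw$run[duplicated(raw$run)]), collapse = ", "))
  }
  neg <- od_response_names()[vapply(od_response_names(),
                                    function(cn) any(raw[[cn]] < 0), logical(1))]
  if (length(neg) > 0L) {
    stop("negative response value(s) in column(s): ", paste(neg, collapse = ", "))
  }
  if (any(raw$WL > 1)) stop("WL values must lie in [0, 1] g/g")
  if (any(raw$DMC > 100)) stop("DMC values must lie in [0, 100] %")
  out <- raw[, c(required, sd_cols)]
  attr(out, "units") <- od_units()
  class(out) <- c("od_design", "data.frame")
  out
}

#' @export
print.od_design <- function(x, ...) {
  cat(sprintf("Dehydration design table: %d runs, %d responses\n",
              nrow(x), length(intersect(od_response_names(), names(x)))))
  print.data.frame(x, ...)
  invisible(x)
}

#' Write a design table to CSV
#'
#' Numeric cells are written with full precision (`format = "%.15g"` via
#' R's default coercion), so writing and re-reading a table reproduces
#' every cell exactly; two successive write/read cycles are byte-identical.
#'
#' @param x an `od_design` table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_design_table <- function(x, path) {
  stopifnot(inherits(x, "od_design"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a table to JSON
#'
#' @param x a data frame (e.g. an `od_design` or score table).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
table_to_json <- function(x, path) {
  jsonlite::write_json(as.data.frame(x), path, dataframe = "rows",
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a storage-stability series
#'
#' Reads a two-arm storage experiment: uncoated (`OD`) and biopolymer-coated
#' (`ODC`) dehydrated samples analysed on days 0, 7, 14, 21 and 28 for
#' acidity, phenols, flavonoids, betaine, DPPH and ABTS. The builtin name
#' `"table4"` loads the packaged series.
#'
#' @param source CSV path or builtin name `"table4"`.
#' @return Named list of two `data.frame`s (one per arm), each of class
#'   `"od_storage"`, ordered by day.
#' @export
load_storage_series <- function(source = "table4") {
  path <- if (identical(source, "table4")) .extdata("table4.csv") else source
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  analytes <- c("acidity", "phenols", "flavonoids", "betaine", "DPPH", "ABTS")
  required <- c("arm", "day", analytes)
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("storage table is missing column(s): ", paste(missing, collapse = ", "))
  }
  sd_cols <- intersect(paste0(analytes, "_sd"), names(raw))
  raw <- .numeric_columns(raw, c("day", analytes, sd_cols), "storage table")
  arms <- unique(raw$arm)
  if (!setequal(arms, c("OD", "ODC"))) {
    stop("storage table must contain exactly the arms 'OD' and 'ODC', got: ",
         paste(arms, collapse = ", "))
  }
  expected_days <- c(0, 7, 14, 21, 28)
  out <- lapply(c(OD = "OD", ODC = "ODC"), function(a) {
    arm <- raw[raw$arm == a, c("day", analytes, sd_cols)]
    miss <- setdiff(expected_days, arm$day)
    if (length(miss) > 0L) {
      stop(sprintf("arm %s is missing day(s): %s", a,
                   paste(miss, collapse = ", ")))
    }
    arm <- arm[order(arm$day), ]
    rownames(arm) <- NULL
    attr(arm, "arm") <- a
    class(arm) <- c("od_storage", "data.frame")
    arm
  })
  out
}

#' Percent change of each analyte over storage
#'
#' For one storage arm, expresses every analyte at every sampling day as
#' the percent change relative to its day-0 baseline:
#' `100 * (value_day - value_0) / value_0`. The day-0 row is zero by
#' construction.
#'
#' @param series one arm as returned by [load_storage_series()].
#' @return Data frame with `day` and one percent-change column per analyte.
#' @examples
#' s <- load_storage_series("table4")
#' retention_summary(s$OD)
#' @export
retention_summary <- function(series) {
  stopifnot(inherits(series, "od_storage"))
  analytes <- setdiff(names(series), c("day", grep("_sd$", names(series), value = TRUE)))
  base <- series[series$day == min(series$day), analytes, drop = FALSE]
  zero <- analytes[vapply(analytes, function(a) base[[a]] == 0, logical(1))]
  if (length(zero) > 0L) {
    stop("percent change undefined: zero day-0 baseline for ",
         paste(zero, collapse = ", "))
  }
  out <- data.frame(day = series$day)
  for (a in analytes) {
    out[[a]] <- 100 * (series[[a]] - base[[a]]) / base[[a]]
  }
  out
}
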
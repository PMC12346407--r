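#' Construct a storage-study design table
#'
#' The experiment table of a concentration-by-time storage study: factors
#' `conc_mg_g` (antioxidant concentration, mg/g) and `time_days`, and the
#' four responses onset temperature `To_C` (degC), activation energy
#' `Ea_kJ_mol` (kJ/mol), peroxide value `PV_meqO2_kg` (meq O2/kg) and the
#' dimensionless `TBA` index.
#'
#' @param df Data frame with (at least) the canonical columns; the response
#'   aliases `Y1`-`Y4` / `To`/`Ea`/`PV`/`TBA` are also understood by the
#'   fitting functions.
#' @return A `design_table` (data frame).
#' @export
design_table <- function(df) {
  df <- as.data.frame(df)
  missing <- setdiff(c("conc_mg_g", "time_days"), names(df))
  if (length(missing)) {
    abort_format(sprintf("design table is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0L) abort_format("design table has no rows")
  have <- intersect(DESIGN_COLS, names(df))
  out <- df[, c(have, setdiff(names(df), have)), drop = FALSE]
  class(out) <- c("design_table", "data.frame")
  out
}

#' @export
print.design_table <- function(x, ...) {
  cat(sprintf("<design_table: %d runs, concentration %g-%g mg/g, days {%s}>\n",
              nrow(x), min(x$conc_mg_g), max(x$conc_mg_g),
              paste(sort(unique(x$time_days)), collapse = ", ")))
  print.data.frame(x, ...)
  invisible(x)
}

#' The packaged 24-run design table
#'
#' The 24-run concentration-by-time design shipped with the package
#' (8 concentration levels crossed with storage days 0, 10 and 30, with the
#' measured concentration at each day), including the four measured responses.
#'
#' @return A `design_table` with 24 rows.
#' @export
design_table7 <- function() {
  path <- system.file("extdata", "design_table7.csv", package = "axstab")
  if (!nzchar(path)) abort_io("packaged design table not found")
  read_design_csv(path)
}

#' Read or write a design-table CSV
#'
#' CSV layout: `conc_mg_g,time_days,To_C,Ea_kJ_mol,PV_meqO2_kg,TBA`.
#'
#' @param path File path.
#' @param x A `design_table`.
#' @export
read_design_csv <- function(path) {
  df <- read_csv_checked(path, DESIGN_COLS)
  design_table(df)
}

#' @rdname read_design_csv
#' @export
write_design_csv <- function(x, path) {
  stopifnot(inherits(x, "design_table"))
  utils::write.csv(as.data.frame(x)[DESIGN_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

resolve_response <- function(table, response) {
  col <- if (response %in% names(RESPONSE_ALIASES)) RESPONSE_ALIASES[[response]] else response
  if (!col %in% names(table)) {
    abort_domain(sprintf("response '%s' not found in the design table", response))
  }
  col
}
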
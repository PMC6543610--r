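#' Belgian male premature-mortality rates, census 2001
#'
#' Under-75 mortality rates per 100,000 person-years for Belgian males by
#' educational level (ISCED-based EL1 lowest to EL4 highest), used as the
#' fixed rate schedule of the composition-shift simulations.
#'
#' @return Named numeric vector of four rates per 100,000 person-years.
#' @examples
#' belgium_rates_2001()
#' @export
belgium_rates_2001 <- function() {
  c(EL1 = 733.8, EL2 = 552.1, EL3 = 450.1, EL4 = 313.9)
}

#' Read / write a stratified rate table
#'
#' The on-disk format is a plain CSV with columns `level_label`, `share` and
#' `rate` (per 100,000 person-years), one row per socio-economic level in
#' ascending order (lowest level first). Synthetic populations add
#' `person_years` and `deaths` columns in the same dialect.
#'
#' @param path Path to a CSV file.
#' @return `read_rate_table()` returns a data frame with the validated
#'   columns; shares are checked to be a proper distribution.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_rate_table(data.frame(level_label = paste0("EL", 1:4),
#'                             share = c(.4, .25, .25, .1),
#'                             rate = c(750, 550, 450, 300)), f)
#' read_rate_table(f)
#' @export
read_rate_table <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  tab <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("malformed CSV '", path, "': ", conditionMessage(e),
                             call. = FALSE))
  need <- c("level_label", "share", "rate")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("'", path, "' is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(tab) < 2L)
    stop("'", path, "' must contain at least 2 levels (has ", nrow(tab), ")",
         call. = FALSE)
  for (col in c("share", "rate")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(tab[[col]]))))
    if (length(bad))
      stop("'", path, "' line ", bad[1] + 1L, ": non-numeric ", col,
           " value '", tab[[col]][bad[1]], "'", call. = FALSE)
    tab[[col]] <- as.numeric(tab[[col]])
  }
  eld(tab$share)                       # validates positivity and sum-to-one
  rate_schedule(tab$rate, tab$share)
  tab
}

#' @rdname read_rate_table
#' @param table Data frame with at least `level_label`, `share`, `rate`.
#' @export
write_rate_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize inequality indices to JSON
#'
#' Emits both full-precision values and the display-rounded rendering (RII
#' and PAF to 2 decimals, SII to the nearest integer) so that downstream
#' consumers can choose their precision policy.
#'
#' @param x An [inequality_indices()] object.
#' @param path Optional path; when given the JSON is written there and the
#'   path returned invisibly, otherwise the JSON string is returned.
#' @export
indices_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "inequality_indices"))
  disp <- format(x)
  obj <- list(
    full_precision = list(sii = x$sii, rii = x$rii, paf = x$paf,
                          intercept = x$intercept, fitted_top = x$fitted_top,
                          mean_rate = x$mean_rate),
    display = list(sii = as.numeric(disp[["sii"]]),
                   rii = suppressWarnings(as.numeric(disp[["rii"]])),
                   paf = as.numeric(disp[["paf"]])),
    shares = x$shares,
    rates = x$rates,
    reference_level = x$reference
  )
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
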
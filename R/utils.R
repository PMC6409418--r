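# internal helpers shared across the package

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pathpos <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "pathpos_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' @importFrom data.table := .N .I .GRP .SD data.table as.data.table setDT
#' @importFrom data.table setorder setorderv rbindlist setnames copy fifelse
#' @importFrom data.table setkey setattr CJ
NULL

# Strict ISO-8601 date parsing. Returns Date with NA for anything that is not
# a real calendar date written as YYYY-MM-DD (so "2001-02-30" fails).
parse_iso_date <- function(x) {
  x <- as.character(x)
  out <- rep(as.Date(NA), length(x))
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  if (any(ok)) {
    d <- as.Date(x[ok], format = "%Y-%m-%d", optional = TRUE)
    # round-trip guard: as.Date() silently folds some impossible dates on
    # certain platforms; formatting back catches them
    d[!is.na(d) & format(d, "%Y-%m-%d") != x[ok]] <- NA
    out[ok] <- d
  }
  out
}

parse_logical <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no", "")] <- FALSE
  out
}

# days between two Date vectors, end - start, whole days
days_between <- function(start, end) {
  as.integer(round(as.numeric(end) - as.numeric(start)))
}

# half-up rounding to whole days (round() in R is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

DAYS_PER_MONTH <- 30.4375
DAYS_PER_YEAR <- 365.25
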
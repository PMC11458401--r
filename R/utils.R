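# Small shared helpers; nothing here is exported.

# Round half away from zero, the convention used for printed percentages.
# base::round() rounds half to even, which differs at exact .xx5 boundaries.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Percentage of n out of total, rounded half-up to 2 decimals.
pct_of <- function(n, total, digits = 2) {
  if (total == 0) return(rep(0, length(n)))
  round_half_up(100 * n / total, digits)
}

# Parse a quarter label like "2020Q2" into (year, quarter).
parse_quarter <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{4})[Qq]([1-4])$", x))[[1]]
  if (length(m) != 3) {
    abort(paste0("invalid quarter label: '", x, "' (expected e.g. '2020Q2')"),
          class = "faersignal_config_error")
  }
  c(year = as.integer(m[2]), quarter = as.integer(m[3]))
}

# First / last calendar date of a quarter label.
quarter_start <- function(x) {
  q <- parse_quarter(x)
  as.Date(sprintf("%d-%02d-01", q["year"], (q["quarter"] - 1L) * 3L + 1L))
}
quarter_end <- function(x) {
  q <- parse_quarter(x)
  if (q["quarter"] == 4L) {
    as.Date(sprintf("%d-12-31", q["year"]))
  } else {
    as.Date(sprintf("%d-%02d-01", q["year"], q["quarter"] * 3L + 1L)) - 1L
  }
}

# Normalize free-text terms: trim, squeeze internal whitespace, case-fold.
norm_term <- function(x) {
  toupper(gsub("[[:space:]]+", " ", trimws(x)))
}

# Dates serialized as YYYYMMDD in the '$' dialect; unparseable -> NA.
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[!grepl("^[0-9]{8}$", x)] <- NA_character_
  as.Date(x, format = "%Y%m%d")
}
format_faers_date <- function(d) {
  out <- format(d, "%Y%m%d")
  out[is.na(out)] <- ""
  out
}

# Numeric parse with silent NA on failure (ages etc.).
parse_num <- function(x) {
  suppressWarnings(as.numeric(x))
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x != floor(x)) {
    abort(paste0("'", name, "' must be a single non-negative integer"),
          class = "faersignal_config_error")
  }
}
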
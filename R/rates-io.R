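#' Read a site-rate table
#'
#' Reads the package's canonical rate-vector file: a UTF-8, LF-terminated TSV
#' with header `locus<TAB>site<TAB>rate<TAB>model`, one row per site, sites
#' 1-based, rows of each locus contiguous, and the literal `NA` in the rate
#' field marking faulty sites. This is the direct-rates entry point: profiles
#' and rankings can be computed from such a file without re-estimating rates.
#'
#' @param path path to the TSV file.
#' @return a `pi_rates` tibble (`locus`, `site`, `rate`, `status`, `loglik`,
#'   `model`); faulty sites have `rate = NA` and `status = "FAULTY"`, all
#'   others `status = "OK"` (`loglik` is not stored in the file and reads back
#'   as `NA`). An empty file yields an empty tibble with a warning.
#' @export
read_rate_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines) || (length(lines) == 1 && grepl("^locus\t", lines[1]))) {
    warning(sprintf("%s contains no rate rows", path), call. = FALSE)
    return(empty_rates())
  }
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(hdr[1:3], c("locus", "site", "rate")))
    stop(sprintf("format error in %s, line 1: expected header 'locus\\tsite\\trate\\tmodel'",
                 path), call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer", "character",
                                         "character")[seq_along(hdr)],
                          na.strings = NULL, quote = "")
  rate <- suppressWarnings(as.numeric(ifelse(df$rate == "NA", NA, df$rate)))
  bad_num <- which(!is.na(df$rate) & df$rate != "NA" & is.na(rate))
  if (length(bad_num))
    stop(sprintf("format error in %s, line %d: unparseable rate '%s'",
                 path, bad_num[1] + 1L, df$rate[bad_num[1]]), call. = FALSE)
  if (any(rate < 0, na.rm = TRUE)) {
    i <- which(rate < 0)[1]
    stop(sprintf("validation error in %s, line %d: negative rate %g",
                 path, i + 1L, rate[i]), call. = FALSE)
  }
  if (anyDuplicated(paste(df$locus, df$site))) {
    i <- which(duplicated(paste(df$locus, df$site)))[1]
    stop(sprintf("validation error in %s, line %d: duplicate (locus, site) = (%s, %d)",
                 path, i + 1L, df$locus[i], df$site[i]), call. = FALSE)
  }
  # loci must be contiguous blocks
  runs <- rle(df$locus)$values
  if (anyDuplicated(runs))
    stop(sprintf("validation error in %s: rows of locus '%s' are not contiguous",
                 path, runs[duplicated(runs)][1]), call. = FALSE)
  out <- tibble::tibble(
    locus = df$locus, site = df$site, rate = rate,
    status = ifelse(is.na(rate), "FAULTY", "OK"),
    loglik = NA_real_,
    model = if ("model" %in% names(df)) df$model else NA_character_
  )
  class(out) <- c("pi_rates", class(out))
  out
}

empty_rates <- function() {
  out <- tibble::tibble(locus = character(), site = integer(),
                        rate = numeric(), status = character(),
                        loglik = numeric(), model = character())
  class(out) <- c("pi_rates", class(out))
  out
}

#' Write a site-rate table
#'
#' Writes rates in the canonical TSV format of [read_rate_table()]. Rates are
#' printed with 17 significant digits so a write/read round trip reproduces
#' the values bitwise; output is locale-independent with LF line endings.
#'
#' @param rates a `pi_rates` tibble (or any data frame with `locus`, `site`,
#'   `rate`, and optionally `model` columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(rates, path) {
  rates <- as_rates(rates)
  model <- if ("model" %in% names(rates)) rates$model else NA_character_
  rows <- sprintf("%s\t%d\t%s\t%s", rates$locus, as.integer(rates$site),
                  num17(rates$rate), ifelse(is.na(model), "", model))
  write_lf(c("locus\tsite\trate\tmodel", rows), path)
}

num17 <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

write_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write a profile spreadsheet
#'
#' Writes the tabulated profile points as CSV with one row per time point and
#' columns `time`, then `<locus>_net` and `<locus>_persite` for each locus,
#' so profiles can be replotted or reanalysed with other software.
#'
#' @param profile a `pi_profile` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profile, path) {
  stopifnot(is.data.frame(profile),
            all(c("time", "locus", "net", "per_site") %in% names(profile)))
  loci <- unique(profile$locus)
  grid <- unique(profile$time)
  wide <- tibble::tibble(time = grid)
  for (lc in loci) {
    sub <- profile[profile$locus == lc, ]
    wide[[paste0(lc, "_net")]] <- sub$net[match(grid, sub$time)]
    wide[[paste0(lc, "_persite")]] <- sub$per_site[match(grid, sub$time)]
  }
  write_csv_plain(wide, path)
}

#' Write an epoch ranking
#'
#' CSV with columns `rank`, `locus`, `t_start`, `t_end`, `integral_net`,
#' `integral_persite`, rows sorted by rank.
#'
#' @param ranking a `pi_ranking` tibble from [rank_loci()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(is.data.frame(ranking),
            all(c("rank", "locus", "integral_net", "integral_persite")
                %in% names(ranking)))
  write_csv_plain(ranking[, c("rank", "locus", "t_start", "t_end",
                              "integral_net", "integral_persite")], path)
}

# Deterministic, locale-independent CSV (full precision, LF endings).
write_csv_plain <- function(df, path) {
  fmt_col <- function(x) {
    if (is.double(x)) num17(x)
    else if (is.logical(x)) ifelse(x, "TRUE", "FALSE")
    else as.character(x)
  }
  cells <- vapply(df, fmt_col, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  rows <- apply(cells, 1, paste, collapse = ",")
  write_lf(c(paste(names(df), collapse = ","), rows), path)
}
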
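#' Threshold configuration for binarization
#'
#' Defaults follow the study conventions: the age cut at 15 years (the
#' median of the 12-18 adolescence window), the income cut at US$780/month
#' (about three minimum wages, the sample median), and one pregnancy as the
#' teenage-pregnancy criterion. Thresholds are inclusive on the upper side:
#' `value >= cut` maps to state 1 for Age and ES.
#'
#' @param age_cut Years (default 15).
#' @param income_cut USD per month (default 780).
#' @param pregnancy_cut Pregnancy count (default 1).
#' @return A `threshold_config` list.
#' @export
threshold_config <- function(age_cut = 15, income_cut = 780,
                             pregnancy_cut = 1) {
  if (any(c(age_cut, income_cut, pregnancy_cut) <= 0)) {
    stop("all threshold cuts must be strictly positive", call. = FALSE)
  }
  structure(list(age_cut = age_cut, income_cut = income_cut,
                 pregnancy_cut = pregnancy_cut),
            class = "threshold_config")
}

raw_columns <- c("age", "sex", "ethnicity", "pregnancy_count",
                 "mother_teen_pregnancy", "enrolled",
                 "family_income_usd_month", "has_job")

binary_columns <- c("Age", "EG", "TP", "MF", "ES", "SS", "LS")

#' Default ethnicity lookup
#'
#' Maps self-declared ethnicity strings (case-insensitively) to the binary
#' white / non-white encoding. Unmapped strings are an error during
#' imputation/binarization, never silently non-white.
#'
#' @return Named integer vector: 0 = white, 1 = non-white.
#' @export
default_ethnicity_map <- function() {
  c(white = 0L, branca = 0L, branco = 0L,
    "non-white" = 1L, nonwhite = 1L, parda = 1L, pardo = 1L,
    preta = 1L, preto = 1L, negra = 1L, negro = 1L, black = 1L,
    brown = 1L, mixed = 1L, indigenous = 1L, indigena = 1L,
    amarela = 1L, asian = 1L)
}

map_ethnicity <- function(x, ethnicity_map) {
  key <- tolower(trimws(x))
  out <- unname(ethnicity_map[key])
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop("unmapped ethnicity value(s): ",
         paste(unique(x[bad]), collapse = ", "),
         "; extend the ethnicity map", call. = FALSE)
  }
  out
}

parse_flag <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA_integer_, length(x))
  out[key %in% c("yes", "y", "1", "true", "sim")] <- 1L
  out[key %in% c("no", "n", "0", "false", "nao", "não")] <- 0L
  out
}

parse_num <- function(x) suppressWarnings(as.numeric(x))

#' Load raw interview records from CSV
#'
#' Expects a header row with the canonical columns `age`, `sex`,
#' `ethnicity`, `pregnancy_count`, `mother_teen_pregnancy`, `enrolled`,
#' `family_income_usd_month`, `has_job`. Unparseable or sentinel cells
#' become explicit missing values; a load report (attribute
#' `"load_report"`) counts missing cells per column. Ages outside the
#' adolescence window \[12, 18\] are rejected.
#'
#' @param path CSV file path.
#' @param delim Field delimiter (default `","`).
#' @param na Strings treated as missing (default empty cell and `"NA"`).
#' @return A `raw_records` data frame, one row per respondent.
#' @export
load_raw_records <- function(path, delim = ",", na = c("", "NA")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.table(path, sep = delim, header = TRUE,
                      colClasses = "character", na.strings = na,
                      check.names = TRUE, stringsAsFactors = FALSE,
                      quote = "\"", comment.char = "", fill = FALSE,
                      encoding = "UTF-8"),
    error = function(e) stop("malformed CSV '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  missing_cols <- setdiff(raw_columns, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  as_raw_records(df[raw_columns])
}

as_raw_records <- function(df) {
  rec <- data.frame(
    age = parse_num(df$age),
    sex = {
      s <- tolower(trimws(as.character(df$sex)))
      s[s %in% c("f", "female", "feminino")] <- "female"
      s[s %in% c("m", "male", "masculino")] <- "male"
      s[!s %in% c("female", "male")] <- NA_character_
      s
    },
    ethnicity = as.character(df$ethnicity),
    pregnancy_count = parse_num(df$pregnancy_count),
    mother_teen_pregnancy = parse_flag(df$mother_teen_pregnancy),
    enrolled = parse_flag(df$enrolled),
    family_income_usd_month = parse_num(df$family_income_usd_month),
    has_job = parse_flag(df$has_job),
    stringsAsFactors = FALSE)
  bad_age <- which(!is.na(rec$age) & (rec$age < 12 | rec$age > 18))
  if (length(bad_age)) {
    stop("age outside the adolescence window [12, 18] in row(s): ",
         paste(utils::head(bad_age, 10), collapse = ", "), call. = FALSE)
  }
  neg <- which(!is.na(rec$pregnancy_count) & rec$pregnancy_count < 0)
  if (length(neg)) {
    stop("negative pregnancy_count in row(s): ",
         paste(utils::head(neg, 10), collapse = ", "), call. = FALSE)
  }
  negi <- which(!is.na(rec$family_income_usd_month) &
                  rec$family_income_usd_month < 0)
  if (length(negi)) {
    stop("negative family_income_usd_month in row(s): ",
         paste(utils::head(negi, 10), collapse = ", "), call. = FALSE)
  }
  attr(rec, "load_report") <- list(
    n_rows = nrow(rec),
    missing = vapply(rec, function(x) sum(is.na(x)), integer(1)))
  class(rec) <- c("raw_records", "data.frame")
  rec
}

#' Write raw records to CSV
#' @param records A `raw_records` data frame.
#' @param path Output path.
#' @export
write_raw_csv <- function(records, path) {
  utils::write.csv(records[raw_columns], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

# median of a 0/1 vector with the documented tie rule: an exact 0.5 median
# rounds down to 0, with a warning.
binary_median <- function(x, column) {
  m <- stats::median(x, na.rm = TRUE)
  if (m == 0.5) {
    warning(sprintf(
      "median of binary column '%s' is tied at 0.5; imputing 0", column),
      call. = FALSE)
    m <- 0
  }
  as.integer(m)
}

#' Impute missing values by column medians
#'
#' Numeric attributes receive the median of the observed values; binary
#' flags (including ethnicity after white/non-white mapping) are encoded
#' 0/1 before taking the median, with an exact 0.5 tie rounded down to 0
#' (warning). Sex, being the downstream exclusion key, is imputed by the
#' column mode instead. Observed values are never altered and row order is
#' preserved.
#'
#' @param records A `raw_records` data frame.
#' @param ethnicity_map Lookup from [default_ethnicity_map()].
#' @return Records with no missing values; attribute `"imputation_report"`
#'   counts imputed cells per column.
#' @export
impute_missing <- function(records, ethnicity_map = default_ethnicity_map()) {
  out <- records
  report <- vapply(records, function(x) sum(is.na(x)), integer(1))
  fully_missing <- names(report)[report == nrow(records)]
  if (length(fully_missing)) {
    stop("cannot impute: column(s) entirely missing: ",
         paste(fully_missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("age", "pregnancy_count", "family_income_usd_month")) {
    i <- is.na(out[[col]])
    if (any(i)) out[[col]][i] <- stats::median(out[[col]], na.rm = TRUE)
  }
  for (col in c("mother_teen_pregnancy", "enrolled", "has_job")) {
    i <- is.na(out[[col]])
    if (any(i)) out[[col]][i] <- binary_median(out[[col]], col)
  }
  i <- is.na(out$ethnicity)
  if (any(i)) {
    eg <- map_ethnicity(out$ethnicity, ethnicity_map)
    out$ethnicity[i] <- c("white", "non-white")[1 + binary_median(eg, "ethnicity")]
  }
  i <- is.na(out$sex)
  if (any(i)) {
    tab <- sort(table(out$sex), decreasing = TRUE)
    out$sex[i] <- names(tab)[1]
  }
  attr(out, "imputation_report") <- report
  attr(out, "load_report") <- attr(records, "load_report")
  out
}

#' Restrict the analysis to female respondents
#'
#' @param records A `raw_records` data frame with `sex` fully observed (run
#'   after [impute_missing()]).
#' @return The female records in their original order.
#' @export
exclude_males <- function(records) {
  if (anyNA(records$sex)) {
    stop("sex must be fully observed before exclusion; impute first",
         call. = FALSE)
  }
  out <- records[records$sex == "female", , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(records)
  out
}

#' Balance classes by random undersampling
#'
#' Splits records into a below-cut and an at-or-above-cut class of
#' `attribute` (by default: never-pregnant versus at least one pregnancy),
#' keeps the minority class whole, and randomly undersamples the majority
#' class without replacement under the given seed. Already balanced input is
#' returned unchanged.
#'
#' @param records A `raw_records` data frame without missing values in
#'   `attribute`.
#' @param attribute Column to balance on (default `"pregnancy_count"`).
#' @param cut Class boundary: class 1 is `value >= cut` (default 1).
#' @param seed Integer seed controlling the random subset.
#' @return Balanced records in original row order; attribute
#'   `"balance_report"` records class sizes and the seed.
#' @export
balance_on_attribute <- function(records, attribute = "pregnancy_count",
                                 cut = 1, seed = 1L) {
  x <- records[[attribute]]
  if (anyNA(x)) stop("missing values in balancing attribute", call. = FALSE)
  cls1 <- which(x >= cut)
  cls0 <- which(x < cut)
  if (!length(cls0) || !length(cls1)) {
    stop("balancing undefined: one class is empty", call. = FALSE)
  }
  n <- min(length(cls0), length(cls1))
  keep <- withr::with_seed(as.integer(seed), {
    c(if (length(cls0) > n) sample(cls0, n) else cls0,
      if (length(cls1) > n) sample(cls1, n) else cls1)
  })
  out <- records[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(records)
  attr(out, "balance_report") <- list(
    attribute = attribute, cut = cut, seed = as.integer(seed),
    class_sizes_before = c(`0` = length(cls0), `1` = length(cls1)),
    class_size_after = n)
  out
}

#' Binarize raw records into the seven analysis attributes
#'
#' Applies the study encoding: `Age` = 1 iff age >= age_cut; `EG` = 0 white,
#' 1 non-white; `TP` = 1 iff pregnancy_count >= pregnancy_cut; `MF` = 1 iff
#' the respondent's mother experienced teenage pregnancy; `ES` = 1 iff
#' family income >= income_cut; `SS` = 1 iff enrolled; `LS` = 1 iff
#' employed. Boundary values fall in the `>=` class.
#'
#' @param records A fully imputed `raw_records` data frame.
#' @param cfg A [threshold_config()].
#' @param ethnicity_map Lookup from [default_ethnicity_map()].
#' @return A data frame with columns `Age, EG, TP, MF, ES, SS, LS`, all 0/1.
#' @export
binarize <- function(records, cfg = threshold_config(),
                     ethnicity_map = default_ethnicity_map()) {
  stopifnot(inherits(cfg, "threshold_config"))
  need <- setdiff(raw_columns, "sex")
  na_cols <- need[vapply(records[need], anyNA, TRUE)]
  if (length(na_cols)) {
    stop("binarize requires complete data; missing values in: ",
         paste(na_cols, collapse = ", "), "; impute first", call. = FALSE)
  }
  out <- data.frame(
    Age = as.integer(records$age >= cfg$age_cut),
    EG = map_ethnicity(records$ethnicity, ethnicity_map),
    TP = as.integer(records$pregnancy_count >= cfg$pregnancy_cut),
    MF = as.integer(records$mother_teen_pregnancy),
    ES = as.integer(records$family_income_usd_month >= cfg$income_cut),
    SS = as.integer(records$enrolled),
    LS = as.integer(records$has_job))
  class(out) <- c("binary_table", "data.frame")
  out
}

#' Write the binary analysis table to CSV
#' @param table A `binary_table`.
#' @param path Output path.
#' @export
write_binary_table <- function(table, path) {
  utils::write.csv(table[binary_columns], path, row.names = FALSE)
  invisible(path)
}

#' Run the full preprocessing protocol
#'
#' Fixed stage order: impute -> exclude males -> balance on teenage
#' pregnancy -> binarize.
#'
#' @param records A `raw_records` data frame.
#' @param cfg A [threshold_config()].
#' @param seed Balancing seed.
#' @param ethnicity_map Lookup from [default_ethnicity_map()].
#' @return List with `table` (the balanced `binary_table`) and `report`
#'   (row counts per stage, imputation counts, the seed).
#' @export
preprocess_pipeline <- function(records, cfg = threshold_config(),
                                seed = 1L,
                                ethnicity_map = default_ethnicity_map()) {
  imputed <- impute_missing(records, ethnicity_map)
  females <- exclude_males(imputed)
  balanced <- balance_on_attribute(females, "pregnancy_count",
                                   cfg$pregnancy_cut, seed)
  table <- binarize(balanced, cfg, ethnicity_map)
  list(table = table,
       report = list(
         n_loaded = nrow(records),
         n_after_imputation = nrow(imputed),
         n_after_exclusion = nrow(females),
         n_after_balancing = nrow(balanced),
         imputed_cells = attr(imputed, "imputation_report"),
         balance = attr(balanced, "balance_report"),
         seed = as.integer(seed)))
}
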
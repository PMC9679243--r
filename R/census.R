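#' @importFrom stats plogis qlogis dnorm rnorm rpois rbinom runif sd var
#'   quantile median cor cor.test logLik coef vcov uniroot qnorm pt setNames
#'   complete.cases as.formula
#' @importFrom utils read.csv write.csv head
NULL

# standard column set for a long-format census table
.census_cols <- c("population", "transect", "quadrat", "plant_id", "year",
                  "diameter_mm", "survival", "fruits")

#' Life-history state labels
#'
#' States of the three-state perennial life cycle plus bookkeeping states:
#' \code{NORMAL} (measurable basal rosette), \code{BOLTER} (alive, reproducing
#' from the terminal bud, no measurable rosette), \code{DORMANT} (alive
#' belowground, inferred from reincarnation patterns), \code{DEAD}, and
#' \code{PRE_RECRUIT} (census years before first observation alive).
#'
#' @return Character vector of the five state labels.
#' @export
lifeStates <- function() c("NORMAL", "BOLTER", "DORMANT", "DEAD", "PRE_RECRUIT")

#' Read a long-format census table
#'
#' Reads a CSV of per-plant, per-year census records and validates it against
#' the schema used throughout the package: one row per (population, transect,
#' quadrat, plant_id, year) with rosette diameter (mm), survival (0/1) and
#' fruit count. Column names in the file can differ from the standard names;
#' supply a \code{dialect} mapping in that case.
#'
#' @param path Path to a CSV file with a header row.
#' @param dialect Named character vector mapping standard column names
#'   (see Details) to the file's column names, e.g.
#'   \code{c(diameter_mm = "ros_diam")}. Unmapped standard names are assumed
#'   to appear verbatim.
#' @param na_codes Strings treated as missing, in addition to empty cells.
#'
#' @details Standard columns: \code{population}, \code{transect},
#'   \code{quadrat}, \code{plant_id}, \code{year}, \code{diameter_mm},
#'   \code{survival}, \code{fruits}.
#'
#' @return A \code{data.frame} of census records with standardized column
#'   names, years as integers, and missing codes mapped to \code{NA}.
#' @export
readCensus <- function(path, dialect = NULL, na_codes = c("NA", "na", "")) {
  if (!file.exists(path)) stop("census file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = na_codes, check.names = FALSE)
  map <- setNames(.census_cols, .census_cols)
  if (!is.null(dialect)) {
    bad <- setdiff(names(dialect), .census_cols)
    if (length(bad))
      stop("dialect maps unknown standard columns: ", paste(bad, collapse = ", "))
    map[names(dialect)] <- unname(dialect)
  }
  missing_cols <- map[!map %in% names(raw)]
  if (length(missing_cols))
    stop("columns not found in ", path, ": ",
         paste(sprintf("%s (for %s)", missing_cols, names(missing_cols)),
               collapse = ", "))
  out <- raw[, unname(map)]
  names(out) <- .census_cols
  out$year <- as.integer(out$year)
  out$diameter_mm <- as.numeric(out$diameter_mm)
  out$survival <- as.integer(out$survival)
  out$fruits <- as.numeric(out$fruits)
  validateCensus(out)
  out
}

#' Validate a census table
#'
#' Checks key uniqueness, value domains and year contiguity. Called by
#' [readCensus()] and by the synthetic-data generator's output contract.
#'
#' @param records Census data.frame with the standard columns.
#' @return Invisibly, \code{records}.
#' @export
validateCensus <- function(records) {
  stopifnot(is.data.frame(records))
  miss <- setdiff(.census_cols, names(records))
  if (length(miss)) stop("census table lacks columns: ", paste(miss, collapse = ", "))
  key <- do.call(paste, c(records[c("population", "transect", "quadrat",
                                    "plant_id", "year")], sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("duplicated (population, transect, quadrat, plant_id, year) keys at rows: ",
         paste(head(dup, 10L), collapse = ", "))
  }
  bad_d <- which(!is.na(records$diameter_mm) & records$diameter_mm < 0)
  if (length(bad_d))
    stop("negative diameter_mm at rows: ", paste(head(bad_d, 10L), collapse = ", "))
  bad_f <- which(!is.na(records$fruits) & records$fruits < 0)
  if (length(bad_f))
    stop("negative fruits at rows: ", paste(head(bad_f, 10L), collapse = ", "))
  bad_s <- which(!is.na(records$survival) & !records$survival %in% c(0L, 1L))
  if (length(bad_s))
    stop("survival not in {0,1} at rows: ", paste(head(bad_s, 10L), collapse = ", "))
  yrs <- sort(unique(records$year))
  if (length(yrs) > 1L && any(diff(yrs) != 1L))
    stop("census years are not consecutive: ", paste(yrs, collapse = ", "),
         " (gaps must be resolved before analysis, not silently imputed)")
  invisible(records)
}

#' Write a census table
#'
#' @param records Census data.frame (standard columns).
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
writeCensus <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Correct "reincarnation" patterns in a survival history
#'
#' A plant recorded dead in one census but alive later was not dead but
#' vegetatively dormant. This correction flips every 0 strictly between the
#' first and last 1 of a binary survival history to 1, so that e.g.
#' \code{"00011101"} becomes \code{"00011111"}. Leading zeros (pre-recruitment)
#' and trailing zeros (after final death) are untouched; the operation is
#' idempotent.
#'
#' @param raw_survival A character string over \{0,1\} (or a vector of such
#'   strings), one character per census year.
#' @return Corrected string(s) of the same length.
#' @export
#' @examples
#' correctReincarnation("00011101")  # "00011111"
correctReincarnation <- function(raw_survival) {
  stopifnot(is.character(raw_survival))
  vapply(raw_survival, function(s) {
    v <- .survival_string_to_int(s)
    paste(.correct_vec(v), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.survival_string_to_int <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  if (length(ch) < 1L) stop("survival history must have length >= 1")
  if (!all(ch %in% c("0", "1")))
    stop("survival history contains non-binary characters: ", s)
  as.integer(ch)
}

# vector kernel: flip zeros flanked by ones; works on 0/1 integer vectors
.correct_vec <- function(v) {
  if (!any(v == 1L)) return(v)
  seen_before <- cummax(v)
  seen_after <- rev(cummax(rev(v)))
  as.integer(seen_before & seen_after)
}

#' Score dormancy by comparing raw and corrected survival histories
#'
#' A census year is flagged dormant exactly where the corrected history says
#' alive but the raw record said dead.
#'
#' @param raw_survival Raw binary survival string.
#' @param corrected_survival Output of [correctReincarnation()] on
#'   \code{raw_survival}.
#' @return Binary flag string of the same length (1 = dormant that year).
#' @export
#' @examples
#' scoreDormancy("00011101", "00011111")  # "00000010"
scoreDormancy <- function(raw_survival, corrected_survival) {
  raw <- .survival_string_to_int(raw_survival)
  cor <- .survival_string_to_int(corrected_survival)
  if (length(raw) != length(cor))
    stop("raw and corrected survival histories differ in length")
  if (!identical(.correct_vec(raw), cor))
    stop("corrected_survival is not the reincarnation correction of raw_survival")
  paste(as.integer(cor == 1L & raw == 0L), collapse = "")
}

#' Classify a plant-year into a life-history state
#'
#' Dormancy (inferred from the reincarnation correction) takes precedence;
#' among the remaining alive plant-years, a missing or zero rosette diameter
#' marks a bolter and a positive diameter a normal rosette.
#'
#' @param alive 0/1, corrected survival in the focal year (vectorized).
#' @param diameter_mm Rosette diameter in mm, \code{NA} when none measured.
#' @param dormant_flag 0/1 dormancy flag for the year.
#' @return Character vector over \{NORMAL, BOLTER, DORMANT, DEAD\}.
#' @export
classifyState <- function(alive, diameter_mm, dormant_flag) {
  n <- max(length(alive), length(diameter_mm), length(dormant_flag))
  alive <- rep_len(as.integer(alive), n)
  diameter_mm <- rep_len(as.numeric(diameter_mm), n)
  dormant_flag <- rep_len(as.integer(dormant_flag), n)
  if (any(dormant_flag == 1L & alive != 1L))
    stop("dormant_flag = 1 requires alive = 1")
  out <- rep("DEAD", n)
  out[alive == 1L] <- "BOLTER"
  out[alive == 1L & !is.na(diameter_mm) & diameter_mm > 0] <- "NORMAL"
  out[dormant_flag == 1L] <- "DORMANT"
  out
}

#' Clean a census table into classified individual histories
#'
#' Applies the reincarnation correction per plant, scores dormancy, classifies
#' every plant-year into \{NORMAL, BOLTER, DORMANT, DEAD, PRE_RECRUIT\}, and
#' canonicalizes bolter sizes (diameter 0 and \code{NA} both mean "no
#' measurable rosette" and are stored as \code{NA}).
#'
#' @param records Census data.frame (standard columns; see [readCensus()]).
#' @return A \code{data.table} of class \code{census_clean}: the input plus
#'   columns \code{plant_uid}, \code{survival_corrected}, \code{dormant},
#'   \code{state}, and \code{recruit_year} (first year observed alive;
#'   \code{NA} for plants never seen alive, which are retained but carry no
#'   transition information).
#' @export
cleanCensus <- function(records) {
  validateCensus(records)
  dt <- data.table::as.data.table(records)
  dt[, plant_uid := paste(population, transect, quadrat, plant_id, sep = "/")]
  data.table::setorder(dt, plant_uid, year)
  dt[, survival_raw := data.table::fifelse(is.na(survival), 0L, as.integer(survival))]
  dt[, survival_corrected := .correct_vec(survival_raw), by = plant_uid]
  dt[, dormant := as.integer(survival_corrected == 1L & survival_raw == 0L)]
  # bolter canonicalization: alive with diameter 0 -> missing size
  dt[survival_corrected == 1L & !is.na(diameter_mm) & diameter_mm == 0,
     diameter_mm := NA_real_]
  dt[, state := classifyState(survival_corrected, diameter_mm, dormant)]
  dt[, recruit_year := {
    alive_years <- year[survival_corrected == 1L]
    if (length(alive_years)) min(alive_years) else NA_integer_
  }, by = plant_uid]
  dt[!is.na(recruit_year) & year < recruit_year, state := "PRE_RECRUIT"]
  data.table::setattr(dt, "class", c("census_clean", class(dt)))
  dt[]
}

#' Cohort-level summary of a cleaned census
#'
#' @param clean A \code{census_clean} table from [cleanCensus()].
#' @return List with \code{n_plants} (unique tagged plants),
#'   \code{n_reincarnates} (plants with at least one dormant year),
#'   \code{n_bolters} (plants with at least one bolter year), and
#'   \code{alive_by_year} (named vector of plants alive per census year,
#'   dormant years counted as alive).
#' @export
summarizeCohort <- function(clean) {
  if (nrow(clean) == 0L)
    return(list(n_plants = 0L, n_reincarnates = 0L, n_bolters = 0L,
                alive_by_year = integer(0)))
  stopifnot(inherits(clean, "census_clean"))
  per <- clean[, .(any_dorm = any(dormant == 1L), any_bolt = any(state == "BOLTER")),
               by = plant_uid]
  alive <- clean[survival_corrected == 1L, .N, by = year]
  data.table::setorder(alive, year)
  list(n_plants = nrow(per),
       n_reincarnates = sum(per$any_dorm),
       n_bolters = sum(per$any_bolt),
       alive_by_year = setNames(alive$N, alive$year))
}

#' Convert a census count to density per square metre
#'
#' Census quadrats are 1 m^2, so density is count divided by the number of
#' quadrats searched.
#'
#' @param count Nonnegative count (vectorized).
#' @param n_quadrats Positive integer number of 1 m^2 quadrats.
#' @return Density in plants per m^2.
#' @export
densityFromCounts <- function(count, n_quadrats) {
  if (any(n_quadrats < 1)) stop("n_quadrats must be >= 1")
  if (any(count < 0, na.rm = TRUE)) stop("count must be nonnegative")
  count / n_quadrats
}

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  "plant_uid", "population", "transect", "quadrat", "plant_id", "year",
  "survival", "survival_raw", "survival_corrected", "dormant", "diameter_mm",
  "state", "recruit_year", "fruits", ".N", "."))
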
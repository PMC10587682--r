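#' Default column mapping for NONMEM-style event datasets
#'
#' Maps internal field names to the column headers conventionally used in
#' NONMEM-style flat files (`ID`, `TIME`, `AMT`, `DV`, `EVID`, `MDV`, `II`,
#' `SS` plus covariate columns). Override entries to load other dialects.
#'
#' @return Named list: internal name -> file column name.
#' @export
default_column_map <- function() {
  list(
    id = "ID", time = "TIME", amt = "AMT", dv = "DV", evid = "EVID",
    mdv = "MDV", ii = "II", ss = "SS",
    weight = "WT", age = "AGE", sex = "SEX", albumin = "ALB",
    daily_dose = "DD", formulation = "FORM",
    cbz = "CBZ", pb = "PB", pht = "PHT", ltg = "LTG", clb = "CLB",
    other_comed = "COMED", uncontrolled_epilepsy = "UNCTRL", pma = "PMA"
  )
}

.sex_levels <- c("male", "female")

decode_sex <- function(x) {
  if (is.numeric(x)) {
    # NONMEM-style numeric coding: 0 = male, 1 = female
    return(ifelse(is.na(x), NA_character_, ifelse(x == 0, "male", "female")))
  }
  x <- tolower(as.character(x))
  x[x %in% c("m", "male", "0")] <- "male"
  x[x %in% c("f", "female", "1")] <- "female"
  x[!x %in% .sex_levels] <- NA_character_
  x
}

decode_formulation <- function(x) {
  if (is.numeric(x)) {
    # 1..6 in the order syrup, sprinkle, capsule, conventional tablet,
    # enteric coated, sustained release
    return(.formulations[ifelse(x %in% seq_along(.formulations), x, NA)])
  }
  x <- tolower(gsub("[ -]", "_", as.character(x)))
  x[x %in% c("sr", "sr_tablet", "sustained_release_tablet")] <- "sustained_release"
  x[x %in% c("ec", "ec_tablet", "enteric", "enteric_coated_tablet")] <- "enteric_coated"
  x[x %in% c("tablet", "conventional")] <- "conventional_tablet"
  x[!x %in% .formulations] <- NA_character_
  x
}

#' Read a NONMEM-style flat dataset into a validated `pk_dataset`
#'
#' Dose rows and observation rows share one long table, discriminated by the
#' event-type column (`EVID`: 1 = dose, 0 = observation). Steady-state trough
#' records are represented as a dose row with `SS = 1` and an interdose
#' interval `II`; this stands in for the full dosing history. Units are fixed
#' at parse time: hours, mg, mg/L (equivalent to ug/mL), g/L for albumin.
#'
#' Subjects missing any of the required covariates (weight, age, sex, daily
#' dose, formulation) are dropped and counted, mirroring the usual exclusion
#' of TDM records with incomplete covariate information; the count is stored
#' in `attr(x, "n_dropped_subjects")`.
#'
#' @param path Path to a CSV file.
#' @param column_map Named list mapping internal names to file column names;
#'   see [default_column_map()].
#' @return A `pk_dataset`: a tibble of events (one row per dose or
#'   observation) carrying per-subject covariates on every row.
#' @export
read_pk_dataset <- function(path, column_map = default_column_map()) {
  if (!file.exists(path)) {
    abort(sprintf("Dataset file not found: '%s'", path),
          class = "vpaeval_io_error")
  }
  raw <- tryCatch(
    readr::read_csv(path, na = c("", "NA", "."), show_col_types = FALSE,
                    progress = FALSE),
    error = function(e) abort(sprintf("Could not read '%s': %s", path,
                                      conditionMessage(e)),
                              class = "vpaeval_io_error")
  )
  cmap <- modifyList(default_column_map(), as.list(column_map))
  df <- tibble::tibble(.rows = nrow(raw))
  for (nm in names(cmap)) {
    col <- cmap[[nm]]
    if (col %in% names(raw)) df[[nm]] <- raw[[col]]
  }
  as_pk_dataset(df, provenance = path)
}

#' Coerce and validate an event table as a `pk_dataset`
#'
#' @param df Data frame with (a subset of) the internal columns `id`, `time`,
#'   `amt`, `dv`, `evid`, `mdv`, `ii`, `ss` and covariates.
#' @param provenance Free-text provenance tag stored as an attribute.
#' @return A validated `pk_dataset` tibble.
#' @export
as_pk_dataset <- function(df, provenance = "in-memory") {
  df <- tibble::as_tibble(df)
  for (nm in c("id", "time", "evid")) {
    if (!nm %in% names(df)) {
      abort(sprintf("Required column '%s' is missing.", nm),
            class = "vpaeval_validation_error")
    }
  }
  df$id <- as.character(df$id)
  numeric_cols <- c("time", "amt", "dv", "evid", "mdv", "ii", "ss",
                    "weight", "age", "albumin", "daily_dose", "pma")
  for (nm in intersect(numeric_cols, names(df))) {
    df[[nm]] <- suppressWarnings(as.numeric(df[[nm]]))
  }
  if (!"amt" %in% names(df)) df$amt <- NA_real_
  if (!"dv" %in% names(df)) df$dv <- NA_real_
  if (!"mdv" %in% names(df)) df$mdv <- ifelse(df$evid == 0, 0, 1)
  if (!"ii" %in% names(df)) df$ii <- NA_real_
  if (!"ss" %in% names(df)) df$ss <- ifelse(df$evid == 1, 1, 0)
  df$ss[is.na(df$ss)] <- 0

  if ("sex" %in% names(df)) df$sex <- decode_sex(df$sex)
  if ("formulation" %in% names(df)) {
    df$formulation <- decode_formulation(df$formulation)
  }
  for (fl in intersect(.flag_cols, names(df))) df[[fl]] <- as_flag(df[[fl]])
  for (fl in setdiff(.flag_cols, names(df))) df[[fl]] <- FALSE

  # Drop subjects with incomplete required covariates (counted, reported)
  required_cov <- c("weight", "age", "sex", "daily_dose", "formulation")
  missing_cols <- setdiff(required_cov, names(df))
  if (length(missing_cols)) {
    abort(sprintf("Required covariate column(s) missing: %s",
                  paste(missing_cols, collapse = ", ")),
          class = "vpaeval_validation_error")
  }
  incomplete <- df |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(bad = any(is.na(.data$weight) | is.na(.data$age) |
                                 is.na(.data$sex) | is.na(.data$daily_dose) |
                                 is.na(.data$formulation)),
                     .groups = "drop")
  dropped <- incomplete$id[incomplete$bad]
  if (length(dropped)) {
    inform(sprintf(
      "Dropped %d subject(s) with missing required covariates: %s",
      length(dropped), paste(head(dropped, 5), collapse = ", ")))
    df <- df[!df$id %in% dropped, , drop = FALSE]
  }
  if (!nrow(df)) {
    abort("No usable rows remain after covariate screening.",
          class = "vpaeval_validation_error")
  }

  # Derived covariates
  df$daily_dose_per_kg <- df$daily_dose / df$weight
  if (!"albumin" %in% names(df)) df$albumin <- NA_real_
  if (!"pma" %in% names(df)) df$pma <- NA_real_
  pma_derived <- is.na(df$pma)
  # Term-birth default: postnatal age in weeks + 40 gestational weeks
  df$pma[pma_derived] <- df$age[pma_derived] * .weeks_per_year + 40
  if (any(pma_derived) && !all(pma_derived)) {
    inform("Postmenstrual age derived from postnatal age for some subjects (term-birth assumption).")
  }

  # Per-subject covariates must be time-constant
  cov_here <- intersect(.covariate_cols, names(df))
  conflicts <- df |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(cov_here),
                                   ~ dplyr::n_distinct(.x) > 1L),
                     .groups = "drop")
  bad <- conflicts[rowSums(as.matrix(conflicts[cov_here])) > 0, ]
  if (nrow(bad)) {
    first <- bad$id[1]
    which_cov <- cov_here[which(unlist(bad[1, cov_here]))[1]]
    abort(sprintf(
      "Subject '%s' carries conflicting values of covariate '%s'.",
      first, which_cov), class = "vpaeval_validation_error")
  }

  # Event-level invariants
  dose_rows <- df$evid == 1
  if (any(dose_rows & (is.na(df$amt) | df$amt <= 0))) {
    abort("Every dose row must have a strictly positive amount.",
          class = "vpaeval_validation_error")
  }
  if (any(dose_rows & df$ss == 1 & (is.na(df$ii) | df$ii <= 0))) {
    abort("Steady-state dose rows must carry a positive interdose interval.",
          class = "vpaeval_validation_error")
  }
  obs_rows <- df$evid == 0 & df$mdv == 0
  if (any(obs_rows & !is.na(df$dv) & df$dv <= 0)) {
    abort("Observed concentrations must be strictly positive.",
          class = "vpaeval_validation_error")
  }

  df <- dplyr::arrange(df, .data$id, .data$time, dplyr::desc(.data$evid))

  # Every observed subject needs a dose at or before its first observation
  per_subj <- split(seq_len(nrow(df)), df$id)
  for (rows in per_subj) {
    sub <- df[rows, ]
    obs_t <- sub$time[sub$evid == 0]
    if (!length(obs_t)) next
    dose_t <- sub$time[sub$evid == 1]
    if (!length(dose_t) || min(dose_t) > min(obs_t)) {
      abort(sprintf(
        "Subject '%s' has observations but no dose event at or before them.",
        sub$id[1]), class = "vpaeval_validation_error")
    }
  }
  if (sum(df$evid == 0) < dplyr::n_distinct(df$id)) {
    warn("Fewer observation rows than subjects; some subjects carry no observations.")
  }

  df$tad <- time_after_dose(df)
  structure(df,
            provenance = provenance,
            n_dropped_subjects = length(dropped),
            class = c("pk_dataset", class(tibble::tibble())))
}

# Time after the most recent dose; steady-state doses wrap modulo the
# interdose interval.
time_after_dose <- function(df) {
  tad <- rep(NA_real_, nrow(df))
  for (rows in split(seq_len(nrow(df)), df$id)) {
    sub <- df[rows, ]
    doses <- sub[sub$evid == 1, ]
    for (i in seq_len(nrow(sub))) {
      if (sub$evid[i] != 0) next
      prior <- doses[doses$time <= sub$time[i], ]
      if (!nrow(prior)) next
      last <- prior[nrow(prior), ]
      dt <- sub$time[i] - last$time
      tad[rows[i]] <- if (last$ss == 1) {
        r <- dt %% last$ii
        if (r == 0 && dt > 0) last$ii else r
      } else dt
    }
  }
  tad
}

#' Write a `pk_dataset` back to NONMEM-style CSV
#'
#' Inverse of [read_pk_dataset()]: `read_pk_dataset(write_pk_dataset(x, f))`
#' reproduces `x` field for field.
#'
#' @param ds A `pk_dataset`.
#' @param path Output CSV path.
#' @param column_map As in [read_pk_dataset()].
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(ds, path, column_map = default_column_map()) {
  cmap <- modifyList(default_column_map(), as.list(column_map))
  out <- tibble::tibble(.rows = nrow(ds))
  for (nm in names(cmap)) {
    if (nm %in% names(ds)) out[[cmap[[nm]]]] <- ds[[nm]]
  }
  out[[cmap$sex]] <- ds$sex
  out[[cmap$formulation]] <- ds$formulation
  for (fl in .flag_cols) {
    nm <- cmap[[fl]] %||% toupper(fl)
    out[[nm]] <- as.integer(ds[[fl]])
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' One covariate row per subject
#'
#' @param ds A `pk_dataset`.
#' @return Tibble with one row per subject holding its (time-constant)
#'   covariates.
#' @export
subject_covariates <- function(ds) {
  ds |>
    dplyr::group_by(.data$id) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(c("id",
                                  intersect(.covariate_cols, names(ds)))))
}

#' Default plausibility bounds for a pediatric valproate TDM cohort
#'
#' Ranges follow the characteristics of a routine pediatric monitoring
#' population: age 0-15 years, weight 4-70 kg, albumin 25-75 g/L, daily dose
#' 5-60 mg/kg/day, concentrations within the assay calibration span.
#'
#' @return Tibble with columns `variable`, `lower`, `upper`.
#' @export
pediatric_bounds <- function() {
  tibble::tribble(
    ~variable,            ~lower, ~upper,
    "age",                0,      15,
    "weight",             4,      70,
    "albumin",            25,     75,
    "daily_dose_per_kg",  5,      60,
    "dv",                 1,      150
  )
}

#' Report covariate values outside plausibility bounds
#'
#' Purely reporting: the dataset is never modified. Widening any bound can
#' only shrink the violation list.
#'
#' @param ds A `pk_dataset`.
#' @param bounds Tibble of `variable`/`lower`/`upper` rows;
#'   default [pediatric_bounds()].
#' @return Tibble with one row per violation: `id`, `variable`, `value`,
#'   `lower`, `upper`.
#' @export
validate_covariates <- function(ds, bounds = pediatric_bounds()) {
  out <- list()
  for (i in seq_len(nrow(bounds))) {
    v <- bounds$variable[i]
    if (!v %in% names(ds)) next
    vals <- if (v == "dv") {
      ds[ds$evid == 0 & ds$mdv == 0, c("id", v)]
    } else {
      unique(ds[, c("id", v)])
    }
    x <- vals[[v]]
    hit <- !is.na(x) & (x < bounds$lower[i] | x > bounds$upper[i])
    if (any(hit)) {
      out[[v]] <- tibble::tibble(id = vals$id[hit], variable = v,
                                 value = x[hit],
                                 lower = bounds$lower[i],
                                 upper = bounds$upper[i])
    }
  }
  if (!length(out)) {
    return(tibble::tibble(id = character(), variable = character(),
                          value = numeric(), lower = numeric(),
                          upper = numeric()))
  }
  dplyr::bind_rows(out)
}

#' @export
print.pk_dataset <- function(x, ...) {
  n_subj <- dplyr::n_distinct(x$id)
  n_obs <- sum(x$evid == 0)
  cat(sprintf("<pk_dataset> %d subjects, %d observations, %d dose events\n",
              n_subj, n_obs, sum(x$evid == 1)))
  NextMethod()
}
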
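#' Covariate table schema
#'
#' Required and optional columns for the per-subject clinical/cognitive
#' record.  A schema config (a named list, or a YAML file with a `columns:`
#' mapping) can rename incoming CSV columns to these canonical names.
#'
#' @keywords internal
covariate_schema <- function() {
  list(
    required = c("id", "age", "sex", "low_education", "gc_z",
                 "sbp", "dbp", "htn_history", "n_antihypertensives",
                 "tiv_cc", "tbv_cc", "wmh_cc",
                 "memory_z", "exec_z", "speed_z", "language_z"),
    numeric  = c("age", "gc_z", "sbp", "dbp", "n_antihypertensives",
                 "tiv_cc", "tbv_cc", "wmh_cc",
                 "memory_z", "exec_z", "speed_z", "language_z"),
    logical  = c("low_education", "htn_history"),
    derived  = c("bp_group", "gmf", "wmh_pct_tiv", "log_wmh")
  )
}

#' Load a per-subject covariate table from CSV
#'
#' Reads a header CSV of clinical and cognitive covariates, optionally
#' renaming columns via a schema config, validates types and basic clinical
#' plausibility (unique ids, positive volumes, wmh <= tbv <= tiv), and adds
#' empty derived columns (`bp_group`, `gmf`, `wmh_pct_tiv`, `log_wmh`) to be
#' filled by [add_derived_covariates()].
#'
#' @param csv_path path to a CSV file with a header row.
#' @param schema_config optional named list or YAML file path; its `columns`
#'   element maps canonical names to the names used in the file, e.g.
#'   `list(columns = list(sbp = "systolic_bp"))`.
#' @return A `data.frame` with canonical columns; `sex` is a factor with
#'   levels `male`, `female`.
#' @export
load_covariates <- function(csv_path, schema_config = NULL) {
  if (is.character(schema_config) && length(schema_config) == 1L)
    schema_config <- yaml::read_yaml(schema_config)
  sch <- covariate_schema()
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  ren <- schema_config$columns
  for (canon in names(ren)) {
    src <- ren[[canon]]
    if (!src %in% names(df))
      stop("schema maps `", canon, "` to missing column `", src, "`")
    names(df)[names(df) == src] <- canon
  }
  missing_cols <- setdiff(sch$required, names(df))
  if (length(missing_cols))
    stop("missing required covariate column(s): ",
         paste(missing_cols, collapse = ", "))

  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    stop("duplicated subject id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  for (col in sch$numeric) {
    v <- df[[col]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(conv))
      if (length(bad))
        stop("non-numeric value in column `", col, "` at row(s) ",
             paste(bad, collapse = ", "))
      v <- conv
    }
    df[[col]] <- as.numeric(v)
  }
  for (col in sch$logical) df[[col]] <- parse_flag(df[[col]], col)
  df$sex <- factor(tolower(as.character(df$sex)), levels = c("male", "female"))
  if (anyNA(df$sex)) stop("`sex` must be coded male/female")

  vols <- c("tiv_cc", "tbv_cc", "wmh_cc")
  for (col in c("tiv_cc", "tbv_cc")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] <= 0)
    if (length(bad))
      stop("non-positive ", col, " at row(s) ", paste(bad, collapse = ", "))
  }
  if (any(df$wmh_cc < 0, na.rm = TRUE)) stop("negative wmh_cc")
  ok <- stats::complete.cases(df[vols])
  if (any(df$wmh_cc[ok] > df$tbv_cc[ok] | df$tbv_cc[ok] > df$tiv_cc[ok]))
    stop("volume ordering violated: require wmh_cc <= tbv_cc <= tiv_cc")

  for (col in sch$derived) df[[col]] <- rep(NA_real_, nrow(df))
  df$bp_group <- factor(rep(NA_character_, nrow(df)),
                        levels = bp_group_levels(), ordered = TRUE)
  df
}

parse_flag <- function(x, name) {
  if (is.logical(x)) return(x)
  out <- rep(NA, length(x))
  xl <- tolower(trimws(as.character(x)))
  out[xl %in% c("true", "t", "1", "yes")] <- TRUE
  out[xl %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(out) && !all(is.na(x)))
    stop("column `", name, "` is not interpretable as TRUE/FALSE")
  out
}

bp_group_levels <- function()
  c("normotensive", "controlled", "uncontrolled", "unclassified")

#' Fill in derived clinical covariates
#'
#' Computes blood-pressure group membership (via [classify_bp_group()]) and
#' the normalized volumetrics (via [derive_volumetrics()]): gray matter
#' fraction GMF = GMV/TBV, WMH as a percent of intracranial volume, and its
#' natural log (`log_wmh`).
#'
#' @param covariates a covariate table from [load_covariates()] (or any
#'   data.frame with the canonical columns).
#' @param gmv_cc optional per-subject total gray matter volume in cc; when
#'   absent `gmf` is left `NA`.
#' @param wmh_floor_cc floor applied to zero WMH volumes before the log;
#'   `NULL` (default) treats a zero as an error.
#' @return The table with `bp_group`, `gmf`, `wmh_pct_tiv`, `log_wmh` filled.
#' @export
add_derived_covariates <- function(covariates, gmv_cc = NULL,
                                   wmh_floor_cc = NULL) {
  df <- covariates
  df$bp_group <- classify_bp_group(df$htn_history,
                                   df$n_antihypertensives > 0,
                                   df$sbp, df$dbp)
  vol <- derive_volumetrics(gmv_cc = gmv_cc, tbv_cc = df$tbv_cc,
                            tiv_cc = df$tiv_cc, wmh_cc = df$wmh_cc,
                            wmh_floor_cc = wmh_floor_cc)
  df$gmf <- vol$gmf
  df$wmh_pct_tiv <- vol$wmh_pct_tiv
  df$log_wmh <- vol$log_wmh
  df
}
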
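#' Construct and validate a longitudinal biomarker table
#'
#' One row per subject x visit x biomarker: columns `id`, `time`, `biomarker`
#' (coded `1..K`), `value`, plus optional baseline covariate columns (constant
#' within subject). Missing values are disallowed; absent measurements are
#' simply absent rows. Subjects with a single visit are allowed.
#'
#' @param df A data frame with at least columns `id`, `time`, `biomarker`,
#'   `value`.
#' @return The validated data frame, ordered by (id, biomarker, time), with
#'   class `"jm_longitudinal"` prepended and attribute `K`.
#' @export
jm_longitudinal <- function(df) {
  req <- c("id", "time", "biomarker", "value")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("longitudinal table is missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("longitudinal table is empty")
  if (anyNA(df[req])) stop("longitudinal table contains missing values")
  if (!all(is.finite(df$time)) || any(df$time < 0))
    stop("visit times must be finite and nonnegative")
  if (!all(df$biomarker == round(df$biomarker)) || any(df$biomarker < 1))
    stop("biomarker index must be a positive integer")
  K <- max(df$biomarker)
  if (!setequal(unique(df$biomarker), seq_len(K)))
    stop("biomarker indices must cover 1..K")
  dup <- duplicated(df[c("id", "time", "biomarker")])
  if (any(dup))
    stop("duplicate (id, time, biomarker) rows, e.g. row ", which(dup)[1])
  df <- df[order(df$id, df$biomarker, df$time), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, K = as.integer(K),
            class = c("jm_longitudinal", class(df)))
}

#' Construct and validate a survival (time-to-event) table
#'
#' One row per subject: `id`, `entry` (left-truncation/delayed-entry time),
#' `time` (observed right-censored time), `event` (0/1), plus baseline
#' covariate columns.
#'
#' @param df A data frame with at least columns `id`, `time`, `event`; an
#'   `entry` column defaults to 0.
#' @return The validated data frame with class `"jm_survival"` prepended.
#' @export
jm_survival <- function(df) {
  if (!("entry" %in% names(df))) df$entry <- 0
  req <- c("id", "entry", "time", "event")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("survival table is missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyNA(df[req])) stop("survival table contains missing values")
  if (anyDuplicated(df$id)) stop("duplicate subject ids in survival table")
  if (!all(df$event %in% c(0, 1))) stop("event indicator must be 0 or 1")
  if (any(df$entry < 0) || any(df$entry > df$time))
    stop("need 0 <= entry <= observed time for every subject")
  df <- df[order(df$id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("jm_survival", class(df)))
}

#' Read and cross-validate a joint dataset from CSV files
#'
#' Reads the longitudinal table (`id,time,biomarker,value,...`) and the
#' survival table (`id,entry,time,event,...`), validates each, and checks the
#' cross references: every longitudinal subject must appear exactly once in
#' the survival table, and no visit may occur after the subject's observed
#' time.
#'
#' @param long_path,surv_path Paths to the two CSV files.
#' @return A list with elements `long` and `surv`.
#' @export
read_joint_data <- function(long_path, surv_path) {
  long <- jm_longitudinal(utils::read.csv(long_path))
  surv <- jm_survival(utils::read.csv(surv_path))
  check_joint_data(long, surv)
  list(long = long, surv = surv)
}

#' @rdname read_joint_data
#' @param long,surv Validated tables from [jm_longitudinal()]/[jm_survival()].
#' @export
check_joint_data <- function(long, surv) {
  orphan <- setdiff(unique(long$id), surv$id)
  if (length(orphan))
    stop("longitudinal subjects missing from survival table: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  tmax <- surv$time[match(long$id, surv$id)]
  bad <- which(long$time > tmax + 1e-8)
  if (length(bad))
    stop("longitudinal rows observed after the subject's event/censoring time: row ",
         paste(utils::head(bad, 5), collapse = ", "))
  invisible(TRUE)
}

#' Write a joint dataset to CSV files
#'
#' @param data A list with `long` and `surv` as returned by
#'   [read_joint_data()] or [jm_simulate()].
#' @param long_path,surv_path Output paths.
#' @export
write_joint_data <- function(data, long_path, surv_path) {
  utils::write.csv(as.data.frame(data$long), long_path, row.names = FALSE)
  utils::write.csv(as.data.frame(data$surv), surv_path, row.names = FALSE)
  invisible(c(long_path, surv_path))
}
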
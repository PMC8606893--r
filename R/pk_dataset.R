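#' Construct a dosing record table
#'
#' @param time Hours since the subject's first dose (numeric vector).
#' @param amount Dose amount in mg (must be positive).
#' @param interval Inter-dose interval in hours; 0 marks a single dose.
#' @param steady_state Logical; TRUE marks a dose given at steady state.
#' @return A `data.frame` with columns `time`, `amount`, `interval`, `ss`.
#' @export
dose_record <- function(time, amount, interval = 0, steady_state = FALSE) {
  stopifnot(all(amount > 0), all(time >= 0), all(interval >= 0))
  data.frame(time = as.numeric(time), amount = as.numeric(amount),
             interval = as.numeric(interval), ss = as.logical(steady_state))
}

#' Construct an observation record table
#'
#' Concentrations are in ng/ml. A row flagged `bql` carries the assay's lower
#' quantitation limit rather than a measured value.
#'
#' @param time Hours since the subject's first dose.
#' @param conc Observed concentration, ng/ml.
#' @param bql Logical below-quantitation-limit flag.
#' @return A `data.frame` with columns `time`, `conc`, `bql`.
#' @export
observation_record <- function(time, conc, bql = FALSE) {
  stopifnot(all(time >= 0))
  bql <- rep_len(as.logical(bql), length(time))
  if (any(conc[!bql] < 0)) stop("negative concentration in non-BQL record")
  data.frame(time = as.numeric(time), conc = as.numeric(conc), bql = bql)
}

#' Construct a single subject's PK data
#'
#' @param subject_id Opaque subject label.
#' @param weight Body weight, kg (positive).
#' @param doses `data.frame` from [dose_record()].
#' @param observations `data.frame` from [observation_record()].
#' @param covariates Named list of extra covariates (age, albumin, ...).
#' @return An object of class `pk_subject`.
#' @export
pk_subject <- function(subject_id, weight, doses, observations,
                       covariates = list()) {
  if (!is.finite(weight) || weight <= 0) stop("weight must be positive")
  if (nrow(observations) > 0 && nrow(doses) == 0)
    stop("subject with observations must have at least one dose")
  doses <- doses[order(doses$time), , drop = FALSE]
  observations <- observations[order(observations$time), , drop = FALSE]
  rownames(doses) <- rownames(observations) <- NULL
  structure(list(subject_id = as.character(subject_id),
                 weight = weight, doses = doses,
                 observations = observations, covariates = covariates),
            class = "pk_subject")
}

#' Construct a longitudinal PK dataset
#'
#' @param subjects List of [pk_subject()] objects with unique ids.
#' @return An object of class `pk_dataset`.
#' @export
pk_dataset <- function(subjects) {
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate subject ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  structure(list(subjects = subjects), class = "pk_dataset")
}

#' @export
print.pk_dataset <- function(x, ...) {
  n_obs <- sum(vapply(x$subjects, function(s) nrow(s$observations), 1L))
  n_dose <- sum(vapply(x$subjects, function(s) nrow(s$doses), 1L))
  cat(sprintf("PK dataset: %d subjects, %d doses, %d observations\n",
              length(x$subjects), n_dose, n_obs))
  invisible(x)
}

#' @export
length.pk_dataset <- function(x) length(x$subjects)

#' Default NONMEM-convention column dialect
#'
#' Maps internal field names to the column names expected in the CSV file.
#' @return Named character vector.
#' @export
nonmem_dialect <- function() {
  c(id = "ID", time = "TIME", amount = "AMT", conc = "DV", evid = "EVID",
    mdv = "MDV", weight = "WT", interval = "II", ss = "SS", bql = "BQL")
}

#' Read a PK dataset from a NONMEM-convention CSV file
#'
#' Dose rows (`EVID == 1`) become dosing records; observation rows
#' (`EVID == 0`, `MDV == 0`) become observation records. Times are in hours
#' from the subject's first dose. The missing-value token is `"."`. Columns
#' beyond the dialect (e.g. `AGE`, `ALB`) are carried per subject as extra
#' covariates, taken from the subject's first row.
#'
#' @param path CSV file path.
#' @param dialect Named map from internal names to column names; see
#'   [nonmem_dialect()]. `II`, `SS` and `BQL` are optional columns.
#' @return A [pk_dataset()].
#' @export
read_pk_dataset <- function(path, dialect = nonmem_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = ".", check.names = FALSE)
  required <- c("id", "time", "amount", "conc", "evid", "mdv", "weight")
  for (f in required) {
    if (!dialect[[f]] %in% names(raw))
      stop("missing required column '", dialect[[f]], "' in ", path)
  }
  num <- function(field, default = NULL) {
    colname <- dialect[[field]]
    if (!colname %in% names(raw)) return(default)
    v <- raw[[colname]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad))
      stop("non-numeric value '", v[bad[1]], "' in column ", colname,
           " at data row ", bad[1])
    out
  }
  id <- raw[[dialect[["id"]]]]
  time <- num("time"); amt <- num("amount"); dv <- num("conc")
  evid <- num("evid"); mdv <- num("mdv"); wt <- num("weight")
  ii <- num("interval", rep(0, nrow(raw)))
  ss <- num("ss", rep(0, nrow(raw)))
  bql <- num("bql", rep(0, nrow(raw)))
  ii[is.na(ii)] <- 0; ss[is.na(ss)] <- 0; bql[is.na(bql)] <- 0

  obs_key <- paste(id, time, evid)[evid == 0 & mdv == 0]
  if (anyDuplicated(obs_key))
    stop("duplicate (ID, TIME, EVID) observation rows: ",
         obs_key[duplicated(obs_key)][1])

  extra_cols <- setdiff(names(raw), unname(dialect))
  subjects <- lapply(unique(id), function(this) {
    rows <- id == this
    is_dose <- rows & evid == 1
    is_obs <- rows & evid == 0 & mdv == 0
    doses <- data.frame(time = time[is_dose], amount = amt[is_dose],
                        interval = ii[is_dose], ss = ss[is_dose] != 0)
    obs <- data.frame(time = time[is_obs], conc = dv[is_obs],
                      bql = bql[is_obs] != 0)
    covs <- lapply(extra_cols, function(cc)
      suppressWarnings(as.numeric(raw[[cc]][rows][1])))
    names(covs) <- extra_cols
    pk_subject(this, wt[rows][1], doses, obs, covs)
  })
  pk_dataset(subjects)
}

#' Write a PK dataset as a NONMEM-convention CSV file
#'
#' Emits the same tabular dialect [read_pk_dataset()] accepts, at full
#' numeric precision, so read-write round trips are lossless.
#'
#' @param ds A [pk_dataset()].
#' @param path Output file path.
#' @param dialect Column-name map, see [nonmem_dialect()].
#' @return Invisibly, `path`.
#' @export
write_pk_dataset <- function(ds, path, dialect = nonmem_dialect()) {
  cov_names <- unique(unlist(lapply(ds$subjects, function(s)
    names(s$covariates))))
  if (length(ds$subjects) == 0) {
    writeLines(paste(c(dialect[c("id", "time", "amount", "conc", "evid",
                                 "mdv", "weight", "interval", "ss", "bql")]),
                     collapse = ","), path)
    return(invisible(path))
  }
  rows <- lapply(ds$subjects, function(s) {
    nd <- nrow(s$doses); no <- nrow(s$observations)
    df <- data.frame(
      id = rep(s$subject_id, nd + no),
      time = c(s$doses$time, s$observations$time),
      amount = c(s$doses$amount, rep(NA_real_, no)),
      conc = c(rep(NA_real_, nd), s$observations$conc),
      evid = c(rep(1, nd), rep(0, no)),
      mdv = c(rep(1, nd), rep(0, no)),
      weight = rep(s$weight, nd + no),
      interval = c(s$doses$interval, rep(0, no)),
      ss = as.numeric(c(s$doses$ss, rep(0, no))),
      bql = as.numeric(c(rep(0, nd), s$observations$bql)))
    for (cc in cov_names)
      df[[cc]] <- rep(if (is.null(s$covariates[[cc]])) NA_real_ else
        s$covariates[[cc]], nd + no)
    df[order(df$time, -df$evid), , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  names(out)[1:10] <- dialect[c("id", "time", "amount", "conc", "evid",
                                "mdv", "weight", "interval", "ss", "bql")]
  # format() would round; write numbers with full double precision
  chr <- as.data.frame(lapply(out, function(col) {
    if (is.numeric(col)) {
      s <- vapply(col, function(v)
        if (is.na(v)) "." else sprintf("%.17g", v), character(1))
      s
    } else as.character(col)
  }), check.names = FALSE)
  utils::write.csv(chr, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a PK dataset
#'
#' Screens for structural problems (unsorted times, nonpositive weight,
#' observations before the first dose, missing observations) and flags
#' concentrations outside the immunoassay's linear range, 3.5-30 ng/ml, as
#' warnings. Findings are returned, never thrown.
#'
#' @param ds A [pk_dataset()].
#' @param assay_range Linear range of the assay, ng/ml.
#' @return `data.frame` with columns `severity` ("error"/"warning"),
#'   `subject`, `message`; zero rows when the dataset is clean.
#' @export
validate_pk_dataset <- function(ds, assay_range = c(3.5, 30)) {
  findings <- list()
  add <- function(severity, subject, message)
    findings[[length(findings) + 1]] <<-
      data.frame(severity = severity, subject = subject, message = message)
  n_obs_total <- 0
  for (s in ds$subjects) {
    n_obs_total <- n_obs_total + sum(!s$observations$bql)
    if (s$weight <= 0)
      add("error", s$subject_id, "nonpositive body weight")
    if (is.unsorted(s$doses$time))
      add("error", s$subject_id, "dose times not sorted")
    if (is.unsorted(s$observations$time))
      add("error", s$subject_id, "observation times not sorted")
    if (nrow(s$observations) > 0 && nrow(s$doses) > 0 &&
        min(s$observations$time) < min(s$doses$time))
      add("error", s$subject_id, "observation before first dose")
    keep <- !s$observations$bql
    low <- s$observations$conc[keep] < assay_range[1]
    high <- s$observations$conc[keep] > assay_range[2]
    if (any(low))
      add("warning", s$subject_id, sprintf(
        "%d observation(s) below assay lower limit %.1f ng/ml",
        sum(low), assay_range[1]))
    if (any(high))
      add("warning", s$subject_id, sprintf(
        "%d observation(s) above assay upper limit %.0f ng/ml",
        sum(high), assay_range[2]))
  }
  if (n_obs_total == 0)
    add("warning", NA_character_, "no observations in dataset")
  if (length(findings) == 0)
    return(data.frame(severity = character(), subject = character(),
                      message = character()))
  do.call(rbind, findings)
}
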
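#' CSV schemas understood by the pipeline
#'
#' @return Named list of schema definitions; each schema lists required
#'   columns with type and range checks.
#' @export
csv_schemas <- function() {
  num <- function(min = -Inf, strict = FALSE)
    list(type = "numeric", min = min, strict = strict)
  chr <- list(type = "character")
  flag <- list(type = "logical")
  list(
    plates = list(
      well = chr, agent_a_conc = num(0), agent_b_conc = num(0),
      mixture_weight_a = list(type = "numeric", min = 0, max = 1,
                              strict = TRUE, allow_na = TRUE),
      raw_signal = num(), is_control = flag, is_blank = flag),
    tumor_volumes = list(
      animal_id = chr, group = chr, day = num(), volume_mm3 = num(0),
      body_weight_g = list(type = "numeric", min = 0, strict = TRUE,
                           optional = TRUE)),
    hematology = list(
      animal_id = chr, group = chr, day = num(),
      platelets_1e9_per_l = num(0, strict = TRUE),
      wbc_1e9_per_l = num(0, strict = TRUE),
      rbc_1e12_per_l = num(0, strict = TRUE)),
    biodistribution = list(
      animal_id = chr, group = chr, organ = chr, time_h = num(0),
      activity_bq = num(0), mass_g = num(0, strict = TRUE),
      injected_bq = num(0, strict = TRUE)),
    tc_table = list(
      model = chr, ttc_kbq_kg = num(0), olaparib_mg_kg = num(0),
      t_over_c = num(0))
  )
}

#' Validate a table against a pipeline CSV schema
#'
#' Checks required columns, cell types, and value ranges, collecting a
#' row-indexed error report rather than stopping at the first problem.
#'
#' @param x data.frame to validate.
#' @param schema schema id, one of `names(csv_schemas())`.
#' @return Object of class `csv_validation`: list with `ok` (logical),
#'   `data` (the table, `NULL` when column checks failed), `errors`
#'   (data.frame `row`, `column`, `message`; `row` is `NA` for table-level
#'   errors), `schema`.
#' @export
validate_table <- function(x, schema) {
  schemas <- csv_schemas()
  if (!schema %in% names(schemas))
    stop("unknown schema '", schema, "'; available: ",
         paste(names(schemas), collapse = ", "), call. = FALSE)
  spec <- schemas[[schema]]
  errors <- data.frame(row = integer(), column = character(),
                       message = character())
  add_err <- function(row, column, message)
    errors <<- rbind(errors, data.frame(row = row, column = column,
                                        message = message))
  required <- names(spec)[!vapply(spec, function(s) isTRUE(s$optional),
                                  logical(1))]
  miss <- setdiff(required, names(x))
  for (m in miss) add_err(NA_integer_, m, "missing required column")
  if (length(miss))
    return(structure(list(ok = FALSE, data = NULL, errors = errors,
                          schema = schema), class = "csv_validation"))
  for (col in intersect(names(spec), names(x))) {
    s <- spec[[col]]
    v <- x[[col]]
    if (s$type == "numeric") {
      if (!is.numeric(v)) {
        add_err(NA_integer_, col, "column is not numeric")
        next
      }
      bad_na <- is.na(v) & !isTRUE(s$allow_na)
      for (i in which(bad_na)) add_err(i, col, "missing value")
      fin <- which(!is.na(v))
      lo <- if (is.null(s$min)) -Inf else s$min
      hi <- if (is.null(s$max)) Inf else s$max
      strict <- isTRUE(s$strict)
      bad <- fin[!is.finite(v[fin]) |
                   (if (strict) v[fin] <= lo else v[fin] < lo) |
                   (if (strict) v[fin] >= hi else v[fin] > hi)]
      for (i in bad)
        add_err(i, col, sprintf("value %s out of range %s%g, %g%s", v[i],
                                if (strict) "(" else "[", lo, hi,
                                if (strict) ")" else "]"))
    } else if (s$type == "logical") {
      ok <- is.logical(v) | (is.numeric(v) & v %in% c(0, 1, NA))
      if (!all(ok)) add_err(NA_integer_, col, "column is not logical (0/1)")
    }
  }
  structure(list(ok = nrow(errors) == 0L,
                 data = if (nrow(errors) == 0L) x else x,
                 errors = errors, schema = schema),
            class = "csv_validation")
}

#' @rdname validate_table
#' @param path path of a CSV file to read and validate.
#' @export
validate_csv <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_table(x, schema)
}

#' @export
print.csv_validation <- function(x, ...) {
  if (x$ok) {
    cat(sprintf("<csv_validation> schema '%s': OK (%d rows)\n",
                x$schema, nrow(x$data)))
  } else {
    cat(sprintf("<csv_validation> schema '%s': %d error(s)\n",
                x$schema, nrow(x$errors)))
    print(x$errors, row.names = FALSE)
  }
  invisible(x)
}

# validate and stop with a readable report on failure
read_validated <- function(input, schema) {
  v <- if (is.character(input)) validate_csv(input, schema)
       else validate_table(input, schema)
  if (!v$ok) {
    msgs <- utils::head(sprintf("row %s, %s: %s", v$errors$row,
                                v$errors$column, v$errors$message), 10L)
    stop("invalid '", schema, "' input:\n  ",
         paste(msgs, collapse = "\n  "), call. = FALSE)
  }
  v$data
}

#' Pipeline run configuration
#'
#' Bundles inputs and analysis settings. Defaults reproduce the standard
#' analysis: inhibition-scale Bliss expectation, 0.10 absolute margin, CI at
#' the 50% effect level, Th-227 half-life 18.7 days.
#'
#' @param plates,tumor_volumes,biodistribution,hematology,tc_table inputs as
#'   CSV paths or data.frames (any subset; `NULL` stages are skipped).
#' @param arms optional arm-dose metadata for Bliss calling (data.frame with
#'   `group`, `ttc_kbq_kg`, `ola_mg_kg`).
#' @param out_dir output directory for reports (`NULL`: no files written).
#' @param convention,margin Bliss settings.
#' @param effect CI effect level.
#' @param vehicle_group,reference_day efficacy settings.
#' @param registry nuclide registry (see [nuclide_registry()]).
#' @param seed seed echoed into the report (the analysis itself is
#'   deterministic).
#' @return Object of class `run_config`.
#' @export
run_config <- function(plates = NULL, tumor_volumes = NULL, arms = NULL,
                       biodistribution = NULL, hematology = NULL,
                       tc_table = NULL, out_dir = NULL,
                       convention = "inhibition-scale", margin = 0.10,
                       effect = 0.5, vehicle_group = "vehicle",
                       reference_day = NULL, registry = nuclide_registry(),
                       seed = 1) {
  structure(list(plates = plates, tumor_volumes = tumor_volumes, arms = arms,
                 biodistribution = biodistribution, hematology = hematology,
                 tc_table = tc_table, out_dir = out_dir,
                 convention = convention, margin = margin, effect = effect,
                 vehicle_group = vehicle_group, reference_day = reference_day,
                 registry = registry, seed = seed),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Validates each supplied input against its schema, runs the applicable
#' stages (in vitro combination index, in vivo efficacy with Bliss calls,
#' Bliss on a printed T/C table, biodistribution summary, hematology
#' summary), and writes machine-readable reports (`ci_report.json`,
#' `isobologram.csv`, `efficacy_report.json`, `biodist_report.csv`) to
#' `out_dir` when set. Every reported number is computed by the underlying
#' module functions; the pipeline layer only orchestrates.
#'
#' @param config a [run_config()].
#' @return list of class `pipeline_report` with elements `invitro`,
#'   `efficacy`, `bliss_table`, `biodist`, `hematology` (stages not run are
#'   `NULL`) and `provenance` (settings echo, package version, seed).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- c("plates", "tumor_volumes", "biodistribution", "hematology",
              "tc_table")
  if (all(vapply(config[inputs], is.null, logical(1))))
    stop("no inputs provided: supply at least one of ",
         paste(inputs, collapse = ", "), call. = FALSE)
  report <- list(invitro = NULL, efficacy = NULL, bliss_table = NULL,
                 biodist = NULL, hematology = NULL)
  th <- config$registry[["Th-227"]]

  if (!is.null(config$plates)) {
    plates <- read_validated(config$plates, "plates")
    report$invitro <- analyze_plates(plates, effect = config$effect)
  }
  if (!is.null(config$tumor_volumes)) {
    tv <- read_validated(config$tumor_volumes, "tumor_volumes")
    report$efficacy <- analyze_efficacy(
      tv, arms = config$arms, vehicle_group = config$vehicle_group,
      reference_day = config$reference_day, convention = config$convention,
      margin = config$margin)
  }
  if (!is.null(config$tc_table)) {
    tc <- read_validated(config$tc_table, "tc_table")
    report$bliss_table <- bliss_from_tc_table(
      tc, convention = config$convention, margin = config$margin)
  }
  if (!is.null(config$biodistribution)) {
    bd <- read_validated(config$biodistribution, "biodistribution")
    summ <- biodist_summary(bd, th)
    tmax <- max(summ$time_h)
    tb <- tryCatch(tumor_to_blood(summ, tmax),
                   error = function(e) list(ratio = NA_real_,
                                            status = conditionMessage(e)))
    report$biodist <- list(summary = summ, tumor_blood_time_h = tmax,
                           tumor_blood_ratio = tb$ratio,
                           tumor_blood_status = tb$status)
  }
  if (!is.null(config$hematology)) {
    hm <- read_validated(config$hematology, "hematology")
    report$hematology <- hematology_summary(hm)
  }
  report$provenance <- list(
    package = "ttcsynergy",
    version = as.character(utils::packageVersion("ttcsynergy")),
    convention = config$convention, margin = config$margin,
    effect = config$effect, vehicle_group = config$vehicle_group,
    seed = config$seed, timestamp = format(Sys.time(), tz = "UTC"))
  class(report) <- "pipeline_report"
  if (!is.null(config$out_dir)) write_reports(report, config$out_dir)
  report
}

# serialize pipeline results to the report files
write_reports <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$invitro)) {
    iv <- report$invitro
    ci_report <- list(
      fit_4pl_a = unclass(iv$fit_4pl_a)[c("top", "bottom", "hill", "ec50",
                                          "absolute_ic50", "ic50_status")],
      fit_4pl_b = unclass(iv$fit_4pl_b)[c("top", "bottom", "hill", "ec50",
                                          "absolute_ic50", "ic50_status")],
      median_effect_a = unclass(iv$fit_me_a)[c("dm", "m", "r_squared")],
      median_effect_b = unclass(iv$fit_me_b)[c("dm", "m", "r_squared")],
      per_ratio_ci = iv$ci$per_ratio, average_ci = iv$ci$average_ci,
      classification = iv$ci$classification,
      n_excluded = iv$ci$n_excluded,
      provenance = report$provenance)
    jsonlite::write_json(ci_report, file.path(out_dir, "ci_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    utils::write.csv(iv$isobologram, file.path(out_dir, "isobologram.csv"),
                     row.names = FALSE)
  }
  eff <- list()
  if (!is.null(report$efficacy)) {
    eff$reference_day <- report$efficacy$reference_day
    eff$t_over_c <- report$efficacy$tc
    eff$doubling_time <- report$efficacy$doubling
    eff$bliss <- report$efficacy$bliss
    eff$censoring <- report$efficacy$study$censoring
  }
  if (!is.null(report$bliss_table)) eff$bliss_printed <- report$bliss_table
  if (!is.null(report$hematology)) eff$hematology <- report$hematology
  if (length(eff)) {
    eff$provenance <- report$provenance
    jsonlite::write_json(eff, file.path(out_dir, "efficacy_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  if (!is.null(report$biodist))
    utils::write.csv(report$biodist$summary,
                     file.path(out_dir, "biodist_report.csv"),
                     row.names = FALSE)
  invisible(NULL)
}

#' @export
print.pipeline_report <- function(x, ...) {
  ran <- names(Filter(Negate(is.null),
                      x[c("invitro", "efficacy", "bliss_table", "biodist",
                          "hematology")]))
  cat("<pipeline_report> stages run:",
      if (length(ran)) paste(ran, collapse = ", ") else "none", "\n")
  invisible(x)
}
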
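#' Expected combination T/C under Bliss additivity
#'
#' Bliss independence assumes the two agents act as statistically
#' independent "hits". On the tumor-growth-inhibition scale, with
#' treatment-over-control ratios `A` and `B` for the two monotherapies, the
#' expected combination T/C under the default `"inhibition-scale"`
#' convention is the product `A * B` -- algebraically identical to applying
#' the textbook Bliss formula `C = A' + B' - A'B'` to the inhibition
#' fractions `A' = 1 - A`, `B' = 1 - B` and mapping back
#' (`1 - C' = A * B`). The `"paper-literal"` convention applies that formula
#' to the T/C ratios themselves, `C = A + B - A*B`; it is retained for
#' comparison but predicts a combination *worse* than either monotherapy and
#' is not used by default.
#'
#' @param a_tc,b_tc monotherapy treatment-over-control ratios in `[0, 1]`
#'   (values in (1, 1.5] are clamped to 1 with a warning; values outside
#'   `[0, 1.5]` are rejected). Vectorized.
#' @param convention `"inhibition-scale"` (default) or `"paper-literal"`.
#' @return Expected combination T/C.
#' @examples
#' bliss_expected(0.8, 0.5)                   # 0.40
#' bliss_expected(0.5, 0.5, "paper-literal")  # 0.75
#' @export
bliss_expected <- function(a_tc, b_tc,
                           convention = c("inhibition-scale", "paper-literal")) {
  convention <- match.arg(convention)
  check_tc <- function(x, lab) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1.5))
      stop("`", lab, "` must be a T/C ratio in [0, 1.5]", call. = FALSE)
    if (any(x > 1)) {
      warning("T/C ratio(s) above 1 clamped to 1 for the Bliss calculation",
              call. = FALSE)
      x <- pmin(x, 1)
    }
    x
  }
  a <- check_tc(a_tc, "a_tc")
  b <- check_tc(b_tc, "b_tc")
  if (convention == "inhibition-scale") a * b else a + b - a * b
}

#' Synergy call from expected versus observed combination T/C
#'
#' Compares the observed combination T/C with the Bliss-expected value using
#' an absolute margin (default 0.10, i.e. ten T/C percentage points):
#' observed below `expected - margin` is synergistic, above
#' `expected + margin` antagonistic, otherwise additive (boundaries fall in
#' the additive class).
#'
#' @param expected_tc expected combination T/C (from [bliss_expected()]).
#' @param observed_tc observed combination T/C.
#' @param margin absolute T/C margin in (0, 0.5].
#' @return Character vector in `{"synergistic", "additive", "antagonistic"}`
#'   (vectorized over its inputs).
#' @examples
#' bliss_call(0.40, 0.10)  # synergistic
#' bliss_call(0.50, 0.45)  # additive
#' @export
bliss_call <- function(expected_tc, observed_tc, margin = 0.10) {
  stopifnot(is.numeric(margin), length(margin) == 1L,
            margin > 0, margin <= 0.5)
  stopifnot(all(is.finite(expected_tc)), all(is.finite(observed_tc)),
            all(expected_tc >= 0), all(observed_tc >= 0))
  eps <- 1e-9  # keep exact boundary values in the additive class
  ifelse(observed_tc < expected_tc - margin - eps, "synergistic",
         ifelse(observed_tc > expected_tc + margin + eps, "antagonistic",
                "additive"))
}

#' Bliss synergy table from a monotherapy/combination T/C table
#'
#' Takes a table of treatment-over-control ratios -- monotherapies and
#' combinations identified by their component doses -- and produces, for
#' every combination row, the Bliss-expected T/C from the matching
#' monotherapy rows and the synergy/additive/antagonism call.
#'
#' @param tc data.frame with columns `model` (cell line / study label),
#'   `ttc_kbq_kg` (agent A dose; 0 when absent), `olaparib_mg_kg` (agent B
#'   dose; 0 when absent) and `t_over_c`. A monotherapy row has exactly one
#'   non-zero dose; a combination row has both.
#' @param convention,margin passed to [bliss_expected()] / [bliss_call()].
#' @return data.frame with one row per combination: `model`, `ttc_kbq_kg`,
#'   `olaparib_mg_kg`, `a_tc`, `b_tc`, `expected_tc`, `observed_tc`, `call`,
#'   `convention`, `margin`.
#' @export
bliss_from_tc_table <- function(tc, convention = "inhibition-scale",
                                margin = 0.10) {
  req <- c("model", "ttc_kbq_kg", "olaparib_mg_kg", "t_over_c")
  miss <- setdiff(req, names(tc))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  combos <- tc[tc$ttc_kbq_kg > 0 & tc$olaparib_mg_kg > 0, , drop = FALSE]
  if (!nrow(combos)) stop("no combination rows in the T/C table", call. = FALSE)
  out <- lapply(seq_len(nrow(combos)), function(i) {
    r <- combos[i, ]
    a <- tc$t_over_c[tc$model == r$model & tc$ttc_kbq_kg == r$ttc_kbq_kg &
                       tc$olaparib_mg_kg == 0]
    b <- tc$t_over_c[tc$model == r$model & tc$ttc_kbq_kg == 0 &
                       tc$olaparib_mg_kg == r$olaparib_mg_kg]
    if (length(a) != 1L || length(b) != 1L)
      stop("no unique monotherapy T/C for combination ", r$model, " ",
           r$ttc_kbq_kg, " kBq/kg + ", r$olaparib_mg_kg, " mg/kg",
           call. = FALSE)
    expd <- bliss_expected(a, b, convention)
    data.frame(model = r$model, ttc_kbq_kg = r$ttc_kbq_kg,
               olaparib_mg_kg = r$olaparib_mg_kg,
               a_tc = a, b_tc = b, expected_tc = expd,
               observed_tc = r$t_over_c,
               call = bliss_call(expd, r$t_over_c, margin),
               convention = convention, margin = margin)
  })
  do.call(rbind, out)
}

#' Printed treatment-over-control summary of the reference combination study
#'
#' Loads the package's shipped fixture of published treatment-over-control
#' ratios for the DLD-1 parental and DLD-1 BRCA2-/- xenograft combination
#' study (three TTC monotherapy activity doses, two olaparib doses, and the
#' four dose combinations per model, with significance labels as printed).
#'
#' @return data.frame with columns `model`, `ttc_kbq_kg`, `olaparib_mg_kg`,
#'   `t_over_c`, `p_label`.
#' @export
dld1_tc_table <- function() {
  path <- system.file("extdata", "dld1_tc_printed.csv",
                      package = "ttcsynergy", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
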
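#' Lateralized MDS-UPDRS III items entering the lateral motor score
#'
#' Seven limb items: leg (rigidity, toe tapping, leg agility) and arm
#' (rigidity, finger tapping, hand movements, pronation/supination).
#' Tremor items are excluded because tremor correlates poorly with
#' dopaminergic deficit.
#' @export
lmsItems <- c("leg_rigidity", "toe_tapping", "leg_agility", "arm_rigidity",
              "finger_tapping", "hand_movements", "pronation_supination")

#' Parameters of the disease-duration adjustment
#'
#' The adjusted disease duration (aDD) linearizes the exponential decline of
#' mean tracer binding with disease duration (DD): raw = exp(rate * DD),
#' re-normalized by an increasing affine map so aDD spans
#' [renorm_min, renorm_max] years as DD does.
#'
#' @param rate per-year exponential coefficient; must be negative.
#'   Default -0.17/year, the value found from the exponential fit of mean
#'   putaminal presynaptic-tracer BR against DD.
#' @param renorm_min,renorm_max renormalization range in years (default 0-16,
#'   the observed DD range).
#' @return a list of class "ADDParams".
#' @export
addParams <- function(rate = -0.17, renorm_min = 0, renorm_max = 16) {
  if (rate >= 0) stopf("rate must be negative (got %g)", rate)
  if (renorm_max <= renorm_min) stopf("renorm_max must exceed renorm_min")
  structure(list(rate = rate, renorm_min = renorm_min,
                 renorm_max = renorm_max), class = "ADDParams")
}

#' Adjusted disease duration
#'
#' Computes aDD = exp(rate * DD) followed by the increasing affine
#' renormalization fixed by the endpoint identities aDD(renorm_min) =
#' renorm_min and aDD(renorm_max) = renorm_max. For renorm_min = 0 this is
#' aDD = renorm_max * (1 - exp(rate * DD)) / (1 - exp(rate * renorm_max)).
#'
#' @param DD disease duration in years (vectorized), >= 0.
#' @param params an \code{\link{addParams}} object.
#' @return aDD in years, same length as DD.
#' @export
computeADD <- function(DD, params = addParams()) {
  if (!inherits(params, "ADDParams")) stopf("params must be addParams()")
  if (any(DD < 0)) stopf("DD must be nonnegative")
  if (any(DD > params$renorm_max))
    warnf("DD above renorm_max (%g years); aDD extrapolated by the same map",
          params$renorm_max)
  e0 <- exp(params$rate * params$renorm_min)
  e1 <- exp(params$rate * params$renorm_max)
  params$renorm_min + (params$renorm_max - params$renorm_min) *
    (e0 - exp(params$rate * DD)) / (e0 - e1)
}

#' Lateral motor score for one body side
#'
#' Sum of the seven lateralized limb items (\code{\link{lmsItems}}); tremor
#' items never contribute.
#'
#' @param items named numeric vector (or one-row data.frame) containing the
#'   seven items, each an integer 0-4.
#' @return integer LMS in [0, 28].
#' @export
computeLMS <- function(items) {
  items <- unlist(items)
  missing <- setdiff(lmsItems, names(items))
  if (length(missing))
    stopf("missing LMS items: %s", paste(missing, collapse = ", "))
  x <- items[lmsItems]
  if (any(!is.finite(x)) || any(x < 0 | x > 4) || any(x != round(x)))
    stopf("LMS items must be integers in 0-4")
  sum(x)
}

#' Assign the worse body side from lateral score totals
#'
#' The body side with the larger lateralized MDS-UPDRS III total is the
#' worse (more affected) side. Ties default to the right body side with a
#' warning (a deterministic, visible convention).
#'
#' @param left_total,right_total nonnegative lateral totals.
#' @return "left" or "right".
#' @export
assignSides <- function(left_total, right_total) {
  if (left_total < 0 || right_total < 0) stopf("lateral totals must be >= 0")
  if (left_total == right_total) {
    warnf("lateral totals tied (%g); defaulting worse body side to right",
          left_total)
    return("right")
  }
  if (left_total > right_total) "left" else "right"
}

#' Exponential fit of mean BR against disease duration
#'
#' Least-squares fit of mean_BR = a * exp(b * DD) by Levenberg-Marquardt,
#' initialized from a log-linear regression. The rate b is the coefficient
#' used by \code{\link{computeADD}}.
#'
#' @param mean_br positive mean BR values, one per subject.
#' @param DD disease durations in years.
#' @return list with elements \code{rate} (b), \code{amplitude} (a),
#'   \code{converged}, and \code{fit} (the nls object).
#' @export
fitADDRate <- function(mean_br, DD) {
  if (length(mean_br) != length(DD)) stopf("mean_br and DD lengths differ")
  if (length(mean_br) < 3) stopf("at least 3 subjects required")
  if (any(mean_br <= 0)) stopf("mean BR values must be positive")
  init <- stats::lm(log(mean_br) ~ DD)
  start <- list(a = exp(unname(stats::coef(init)[1])),
                b = unname(stats::coef(init)[2]))
  # a zero-residual log-linear fit is already the exact solution; the
  # Levenberg-Marquardt refinement has nothing to improve there
  rss0 <- sum((mean_br - start$a * exp(start$b * DD))^2)
  if (rss0 < 1e-16 * sum(mean_br^2))
    return(list(rate = start$b, amplitude = start$a, converged = TRUE,
                fit = init))
  fit <- tryCatch(
    minpack.lm::nlsLM(mean_br ~ a * exp(b * DD), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stopf("exponential fit failed to converge: %s",
                              conditionMessage(e), class = "pclasso_fit_error"))
  co <- stats::coef(fit)
  list(rate = unname(co["b"]), amplitude = unname(co["a"]),
       converged = fit$convInfo$isConv %||% TRUE, fit = fit)
}

# Columns that must be present in any clinical table.
.mandatoryClinical <- c("subject_id", "group", "DD")
.optionalCovariates <- c("age", "AgLED", "agonist_status", "sex")

.sideItemCols <- function(side) paste0(lmsItems, "_", side)

#' Read and validate a clinical table
#'
#' Parses a CSV clinical table and derives missing quantities where
#' possible: per-side LMS from the seven lateralized items, the worse body
#' side from lateralized totals (all lateralized item columns present in the
#' table, configurable), and aDD from DD.
#'
#' Mandatory columns: subject_id, group (HC/PD), DD (years). Optional:
#' age, AgLED, agonist_status, sex, per-side item columns
#' (\code{<item>_left}, \code{<item>_right}), LMS_better, LMS_worse,
#' worse_body_side, aDD. Absent optional covariates are recorded in the
#' "absent_covariates" attribute.
#'
#' @param path CSV file path.
#' @param add_params \code{\link{addParams}} used when aDD must be derived.
#' @param side_items character vector of item stems used for the lateral
#'   totals in side assignment; defaults to all lateralized item columns
#'   found in the table.
#' @return a validated data.frame (one row per subject).
#' @export
readClinicalTable <- function(path, add_params = addParams(),
                              side_items = NULL) {
  if (!file.exists(path)) stopf("clinical table not found: %s", path)
  tab <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e)
                    stopf("malformed clinical CSV: %s", conditionMessage(e),
                          class = "pclasso_format_error"))
  missing <- setdiff(.mandatoryClinical, names(tab))
  if (length(missing))
    stopf("missing mandatory clinical columns: %s",
          paste(missing, collapse = ", "), class = "pclasso_format_error")
  if (any(tab$DD < 0)) stopf("DD must be nonnegative")
  if (!all(tab$group %in% c("HC", "PD")))
    stopf("group must be HC or PD")

  itemCols <- intersect(c(.sideItemCols("left"), .sideItemCols("right")),
                        names(tab))
  for (cc in itemCols) {
    x <- tab[[cc]]
    if (any(!is.finite(x)) || any(x < 0 | x > 4) || any(x != round(x)))
      stopf("item scores in column %s must be integers in 0-4", cc)
  }

  haveL <- all(.sideItemCols("left") %in% names(tab))
  haveR <- all(.sideItemCols("right") %in% names(tab))
  if (is.null(tab$worse_body_side) && haveL && haveR) {
    stems <- side_items %||%
      unique(sub("_(left|right)$", "", itemCols))
    lt <- rowSums(tab[, paste0(stems, "_left"), drop = FALSE])
    rt <- rowSums(tab[, paste0(stems, "_right"), drop = FALSE])
    tab$worse_body_side <- mapply(assignSides, lt, rt)
  }
  if (is.null(tab$LMS_better) && haveL && haveR &&
      !is.null(tab$worse_body_side)) {
    lmsL <- apply(tab[, .sideItemCols("left"), drop = FALSE], 1, sum)
    lmsR <- apply(tab[, .sideItemCols("right"), drop = FALSE], 1, sum)
    worseIsLeft <- tab$worse_body_side == "left"
    tab$LMS_worse <- ifelse(worseIsLeft, lmsL, lmsR)
    tab$LMS_better <- ifelse(worseIsLeft, lmsR, lmsL)
  }
  for (cc in intersect(c("LMS_better", "LMS_worse"), names(tab)))
    if (any(tab[[cc]] < 0 | tab[[cc]] > 28))
      stopf("%s outside [0, 28]", cc)
  if (is.null(tab$aDD)) tab$aDD <- computeADD(tab$DD, add_params)

  attr(tab, "absent_covariates") <- setdiff(.optionalCovariates, names(tab))
  attr(tab, "add_params") <- add_params
  tab
}
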
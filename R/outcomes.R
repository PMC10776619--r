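#' Lifetime cancer probability without prophylactic surgery
#'
#' Sum of the breast-only, ovarian-only and both-cancers risks in the
#' no-surgery stratum (central scenario: 0.49 + 0.09 + 0.215 = 0.795). This
#' is the probability applied to carriers unaware of their status.
#'
#' @param risks Cancer-risk matrix (rows = surgery strata).
#' @return Probability in [0, 1].
#' @export
cancer_prob_no_surgery <- function(risks) {
  sum(risks["none", c("breast_only", "ovarian_only", "both_cancers")])
}

#' Lifetime cancer probability for carriers aware before cancer onset
#'
#' Aware carriers choose a prophylactic-surgery option with the uptake
#' probabilities in `mix`; each surgery stratum carries its own residual
#' lifetime cancer risk. The result is the mix-weighted total cancer
#' probability (central: 0.37866).
#'
#' @param mix Surgery-uptake probabilities named by stratum.
#' @param risks Cancer-risk matrix (rows = surgery strata).
#' @return Probability in [0, 1].
#' @export
cancer_prob_aware <- function(mix, risks) {
  cancer_cols <- c("breast_only", "ovarian_only", "both_cancers")
  sum(mix[SURGERY_STRATA] * rowSums(risks[SURGERY_STRATA, cancer_cols, drop = FALSE]))
}

#' Expected cancers and healthy life-years lost for one generation
#'
#' Converts a detection result into expected cancer counts. Detected (aware)
#' carriers face the surgery-mix-weighted risks; undetected carriers face the
#' no-surgery risks. The by-type decomposition counts breast-involved and
#' ovarian-involved cancers (patients with both cancers appear once in each
#' involvement total; inclusion-exclusion recovers the case count). Healthy
#' life-years lost are cancer cases times the years between the average
#' cancer onset age and model exit at 80 - the published tables label this
#' quantity "DALY", with no disability weights or discounting.
#'
#' @param detection A `brca_detection`.
#' @param params A `brca_scenario`.
#' @return A `brca_cancer_outcome` list: `cancers_aware`, `cancers_unaware`,
#'   `cancers_total`, involvement counts split by awareness, and `hly_lost`.
#' @export
expected_cancers <- function(detection, params) {
  stopifnot(inherits(detection, "brca_detection"), inherits(params, "brca_scenario"))
  risks <- params$cancer_risks
  mix <- params$surgery_mix

  # per-carrier involvement rates: breast = breast_only + both, etc.
  aware_rate <- function(cols) sum(mix[SURGERY_STRATA] *
    rowSums(risks[SURGERY_STRATA, cols, drop = FALSE]))
  unaware_rate <- function(cols) sum(risks["none", cols])

  nd <- detection$carriers_detected
  nu <- detection$carriers_undetected
  cancer_cols <- c("breast_only", "ovarian_only", "both_cancers")

  out <- list(
    cancers_aware = nd * aware_rate(cancer_cols),
    cancers_unaware = nu * unaware_rate(cancer_cols),
    breast_involved_aware = nd * aware_rate(c("breast_only", "both_cancers")),
    ovarian_involved_aware = nd * aware_rate(c("ovarian_only", "both_cancers")),
    both_aware = nd * aware_rate("both_cancers"),
    breast_involved_unaware = nu * unaware_rate(c("breast_only", "both_cancers")),
    ovarian_involved_unaware = nu * unaware_rate(c("ovarian_only", "both_cancers")),
    both_unaware = nu * unaware_rate("both_cancers")
  )
  out$cancers_total <- out$cancers_aware + out$cancers_unaware
  out$breast_involved <- out$breast_involved_aware + out$breast_involved_unaware
  out$ovarian_involved <- out$ovarian_involved_aware + out$ovarian_involved_unaware
  out$both_cancers <- out$both_aware + out$both_unaware
  out$hly_lost <- out$cancers_total * params$timeline$fu_step2_years
  structure(out, class = "brca_cancer_outcome")
}

#' @export
print.brca_cancer_outcome <- function(x, ...) {
  cat(sprintf("Expected cancers: %.1f (aware %.1f, unaware %.1f); HLY lost (paper: DALY): %.0f\n",
              x$cancers_total, x$cancers_aware, x$cancers_unaware, x$hly_lost))
  invisible(x)
}
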
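#' HOMA-IR score
#'
#' Homeostatic model assessment of insulin resistance from fasting values:
#' (glucose mg/dL x insulin mU/L) / 405.
#'
#' @param glucose_mg_dl fasting blood glucose, mg/dL (> 0).
#' @param insulin_mU_L fasting insulin, mU/L (> 0).
#' @return numeric HOMA-IR score(s).
#' @export
homa_ir <- function(glucose_mg_dl, insulin_mU_L) {
  if (any(glucose_mg_dl <= 0, na.rm = TRUE) ||
      any(insulin_mU_L <= 0, na.rm = TRUE))
    stop("glucose and insulin must be positive")
  glucose_mg_dl * insulin_mU_L / 405
}

#' Upper limit of normal HOMA-IR in this model system
#' @export
HOMA_IR_THRESHOLD <- 13.2

#' Insulin-resistance call from three criteria
#'
#' A subject is insulin-resistant when at least two of three criteria hold:
#' elevated HOMA-IR (strictly above 13.2), impaired glucose tolerance
#' (IPGTT), impaired insulin sensing (IPITT). The tolerance-test
#' impairments are clinical judgments supplied as inputs.
#'
#' @param homa_elevated,gtt_impaired,itt_impaired logical vectors.
#' @return logical vector.
#' @export
classify_ir <- function(homa_elevated, gtt_impaired, itt_impaired) {
  (as.integer(homa_elevated) + as.integer(gtt_impaired) +
     as.integer(itt_impaired)) >= 2L
}

#' NAFLD diagnostic flag
#'
#' Diagnostic for NAFLD when the NAFLD activity score is strictly above 5
#' and fibrosis is present.
#'
#' @param nas_score NAFLD activity score.
#' @param fibrosis_present logical.
#' @return logical vector.
#' @export
nafld_flag <- function(nas_score, fibrosis_present) {
  nas_score > 5 & as.logical(fibrosis_present)
}

#' Censored-glucometer clamping
#'
#' Glucose tolerance curves above the glucometer detection limit are
#' recorded as the limit (500 mg/dL); insulin-tolerance rescue values are
#' recorded as 20 mg/dL. Values supplied as strings flagged with ">" are
#' clamped accordingly.
#'
#' @param values numeric or character vector (character entries may carry a
#'   leading ">").
#' @param kind \code{"gtt"} (clamp at 500) or \code{"itt"} (rescue 20).
#' @return numeric vector.
#' @export
censor_glucose <- function(values, kind = c("gtt", "itt")) {
  kind <- match.arg(kind)
  lim <- if (kind == "gtt") 500 else 20
  if (is.character(values)) {
    flagged <- grepl("^>", values)
    out <- suppressWarnings(as.numeric(sub("^>", "", values)))
    out[flagged] <- lim
    return(out)
  }
  if (kind == "gtt") pmin(values, lim) else values
}

#' Metabolic flags per subject
#'
#' Combines HOMA-IR, tolerance-test impairments and liver scoring into the
#' per-subject flag set used as the disease label downstream
#' (NAFLD or insulin resistance).
#'
#' @param glucose_mg_dl,insulin_mU_L fasting values.
#' @param gtt_impaired,itt_impaired logical criteria (inputs).
#' @param nas_score,fibrosis_present liver histology scoring.
#' @return data.frame: \code{homa_ir}, \code{homa_elevated},
#'   \code{insulin_resistant}, \code{nafld}, \code{diseased}.
#' @export
metabolic_flags <- function(glucose_mg_dl, insulin_mU_L,
                            gtt_impaired, itt_impaired,
                            nas_score, fibrosis_present) {
  h <- homa_ir(glucose_mg_dl, insulin_mU_L)
  he <- h > HOMA_IR_THRESHOLD
  ir <- classify_ir(he, gtt_impaired, itt_impaired)
  na <- nafld_flag(nas_score, fibrosis_present)
  data.frame(homa_ir = h, homa_elevated = he, insulin_resistant = ir,
             nafld = na, diseased = ir | na)
}

#' Next-timepoint weight response
#'
#' For each sample, the subject's weight at the next later measurement
#' ("Weight + 1"); the last measurement of each subject has no successor
#' and is returned as NA (to be excluded from the response matrix).
#' Ordering, not spacing, defines "next".
#'
#' @param weights weight per sample.
#' @param subjects subject id per sample.
#' @param weeks measurement week per sample.
#' @return numeric vector aligned with the input samples.
#' @export
weight_plus_one <- function(weights, subjects, weeks) {
  n <- length(weights)
  if (length(subjects) != n || length(weeks) != n)
    stop("weights, subjects, weeks must be aligned")
  out <- rep(NA_real_, n)
  for (s in unique(subjects)) {
    idx <- which(subjects == s)
    ord <- idx[order(weeks[idx])]
    if (length(ord) > 1L)
      out[ord[-length(ord)]] <- weights[ord[-1L]]
  }
  out
}
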
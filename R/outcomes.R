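# Scoring and diagnosis rules for the three APNS instruments:
# PCL-5 (PTSD), PROMIS Depression 8b (t-score), Rivermead somatic count.

#' Score the PCL-5 PTSD checklist
#'
#' Sum of the 20 item responses, each scored 0--4, giving a raw score in
#' 0--80.
#'
#' @param items integer vector of exactly 20 item responses in 0--4.
#' @return integer raw score.
#' @export
score_pcl5 <- function(items) {
  if (length(items) != 20)
    stop("validation error: PCL-5 has exactly 20 items, got ", length(items))
  if (any(!is.finite(items)) || any(items != as.integer(items)) ||
      any(items < 0) || any(items > 4))
    stop("validation error: PCL-5 items must be integers in 0-4")
  as.integer(sum(items))
}

#' PTSD diagnosis from a PCL-5 raw score
#'
#' Positive when the raw score exceeds the cut point (default 31, strict
#' greater-than: the analysis groups are "raw score <= 31" vs "> 31").
#'
#' @param pcl5_raw raw score(s) in 0--80.
#' @param cut diagnostic cut point (default 31).
#' @return logical vector.
#' @export
diagnose_ptsd <- function(pcl5_raw, cut = 31) {
  if (any(!is.finite(pcl5_raw)) || any(pcl5_raw < 0) || any(pcl5_raw > 80))
    stop("validation error: PCL-5 raw score must lie in 0-80")
  pcl5_raw > cut
}

#' Depression diagnosis from a PROMIS 8b t-score
#'
#' Positive when the t-score is at or above the cut (default 60, one
#' standard deviation above the population mean of 50).
#'
#' @param promis_t t-score(s).
#' @param cut diagnostic cut point (default 60).
#' @return logical vector.
#' @export
diagnose_depression <- function(promis_t, cut = 60) {
  if (any(!is.finite(promis_t)))
    stop("validation error: non-finite t-score")
  promis_t >= cut
}

#' Count somatic symptoms from Rivermead yes/no responses
#'
#' @param responses logical vector of exactly 12 yes/no symptom responses.
#' @return integer count in 0--12.
#' @export
count_somatic <- function(responses) {
  if (length(responses) != 12)
    stop("validation error: expected 12 symptom responses, got ",
         length(responses))
  if (!is.logical(responses) || anyNA(responses))
    stop("validation error: responses must be TRUE/FALSE")
  as.integer(sum(responses))
}
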
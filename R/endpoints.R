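# Endpoint derivation --------------------------------------------------------
#
# OS:     time from induction start to death (event) or last follow-up
#         (censored). SCT never censors anything.
# EFS:    non-CR patients are events (non-achievement) at the induction
#         failure assessment time; CR patients are events at the first of
#         relapse or death, else censored at last follow-up.
# Relapse: clock restarts at the CR date; relapse = cause 1, death without
#         prior relapse = cause 2, else censored; defined for CR patients
#         only.

#' Derive survival endpoints from clinical records
#'
#' @param clinical validated clinical data.frame ([read_clinical_table()]
#'   dialect); validated again here.
#' @param noncr_efs_time months at which CR non-achievement counts as the
#'   EFS event for patients who never achieved CR (their recorded death or
#'   last follow-up is used when it is earlier). Default 1 month, the
#'   failure-assessment point after one induction course.
#' @return data.frame with one row per patient: `patient_id`, `os_time`,
#'   `os_event`, `efs_time`, `efs_event`, `relapse_entry`, `relapse_time`
#'   (months since CR), `relapse_code` (0 censored, 1 relapse, 2 death
#'   without relapse; NA for non-CR patients).
#' @export
derive_endpoints <- function(clinical, noncr_efs_time = 1) {
  validate_clinical(clinical)
  if (!(is.numeric(noncr_efs_time) && noncr_efs_time >= 0)) {
    stop("noncr_efs_time must be a non-negative number of months",
         call. = FALSE)
  }
  n <- nrow(clinical)
  out <- data.frame(
    patient_id = clinical$patient_id,
    os_time = NA_real_, os_event = NA,
    efs_time = NA_real_, efs_event = NA,
    relapse_entry = NA_real_, relapse_time = NA_real_,
    relapse_code = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    r <- clinical[i, ]
    death <- r$death_time
    lfu <- r$last_followup_time
    out$os_time[i] <- if (!is.na(death)) death else lfu
    out$os_event[i] <- !is.na(death)
    if (isTRUE(r$cr_achieved)) {
      ev <- c(relapse = r$relapse_time, death = death)
      if (any(!is.na(ev))) {
        out$efs_time[i] <- min(ev, na.rm = TRUE)
        out$efs_event[i] <- TRUE
      } else {
        out$efs_time[i] <- lfu
        out$efs_event[i] <- FALSE
      }
      cr <- r$cr_time
      out$relapse_entry[i] <- cr
      if (!is.na(r$relapse_time)) {
        out$relapse_time[i] <- r$relapse_time - cr
        out$relapse_code[i] <- 1L
      } else if (!is.na(death)) {
        out$relapse_time[i] <- death - cr
        out$relapse_code[i] <- 2L
      } else {
        out$relapse_time[i] <- lfu - cr
        out$relapse_code[i] <- 0L
      }
    } else {
      # non-achievement of CR is itself the EFS event
      out$efs_time[i] <- min(noncr_efs_time, death, lfu, na.rm = TRUE)
      out$efs_event[i] <- TRUE
    }
  }
  out
}

#' Expand records into start-stop intervals with a time-dependent SCT flag
#'
#' Builds the counting-process representation used by
#' [cox_time_dependent()]: patients transplanted before their (OS or EFS)
#' endpoint contribute an interval with `sct = 0` up to the transplant date
#' and one with `sct = 1` from then on; everyone else contributes a single
#' unexposed interval. Transplants at or after the endpoint never count as
#' exposure.
#'
#' @param clinical validated clinical data.frame.
#' @param endpoints output of [derive_endpoints()] for the same patients;
#'   derived on the fly when `NULL`.
#' @param endpoint `"os"` or `"efs"`.
#' @return data.frame with `patient_id`, `start`, `stop`, `event`, `sct`.
#' @export
make_sct_intervals <- function(clinical, endpoints = NULL,
                               endpoint = c("os", "efs")) {
  endpoint <- match.arg(endpoint)
  if (is.null(endpoints)) endpoints <- derive_endpoints(clinical)
  stopifnot(identical(clinical$patient_id, endpoints$patient_id))
  tm <- endpoints[[paste0(endpoint, "_time")]]
  ev <- endpoints[[paste0(endpoint, "_event")]]
  rows <- lapply(seq_len(nrow(clinical)), function(i) {
    sct <- clinical$sct_time[i]
    if (!is.na(sct) && sct > 0 && sct < tm[i]) {
      data.frame(patient_id = clinical$patient_id[i],
                 start = c(0, sct), stop = c(sct, tm[i]),
                 event = c(FALSE, ev[i]), sct = c(0L, 1L),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(patient_id = clinical$patient_id[i],
                 start = 0, stop = tm[i], event = ev[i], sct = 0L,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out[out$stop > out$start, , drop = FALSE]
}
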
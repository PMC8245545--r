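# Cohort bookkeeping: per-condition video and post-barrier ROI counts, with
# the internal-consistency identities every run report must satisfy.

#' Per-condition video / post-barrier ROI count table
#'
#' Builds the run-report bookkeeping table: one row per condition plus a
#' pooled disease (RHHA) row and a grand total, mirroring how such cohorts
#' are reported (e.g. 79 videos / 3442 post-barrier ROIs split into control
#' and the SCD/THAL/HS subtypes).
#'
#' @param video_conditions named character vector: condition per video id.
#' @param roi_video_ids character vector with one entry per counted ROI
#'   (typically post-barrier ROIs only).
#' @return Data frame with columns `sample`, `n_videos`, `n_rois`.
#' @export
roi_count_table <- function(video_conditions, roi_video_ids) {
  per_video <- table(factor(roi_video_ids, levels = names(video_conditions)))
  conds <- rhha_conditions()
  n_vid <- vapply(conds, function(cc) sum(video_conditions == cc), integer(1))
  n_roi <- vapply(conds, function(cc)
    sum(per_video[names(video_conditions)[video_conditions == cc]]), numeric(1))
  rhha <- conds[conds != "healthy"]
  data.frame(
    sample = c("Total", "Control", "RHHA", rhha),
    n_videos = c(sum(n_vid), n_vid[["healthy"]], sum(n_vid[rhha]),
                 unname(n_vid[rhha])),
    n_rois = as.integer(c(sum(n_roi), n_roi[["healthy"]], sum(n_roi[rhha]),
                          unname(n_roi[rhha]))),
    stringsAsFactors = FALSE)
}

#' Validate the count-table identities
#'
#' Enforces, on any cohort table shaped like [roi_count_table()]'s output:
#' Control + RHHA = Total and SCD + THAL + HS = RHHA, for both video and ROI
#' counts.
#'
#' @param tbl data frame with columns `sample`, `n_videos`, `n_rois`.
#' @return `TRUE` invisibly; otherwise a consistency error.
#' @export
validate_roi_table <- function(tbl) {
  g <- function(s, col) tbl[[col]][match(s, tbl$sample)]
  for (col in c("n_videos", "n_rois")) {
    if (g("Control", col) + g("RHHA", col) != g("Total", col)) {
      abort(sprintf("%s: Control + RHHA != Total", col),
            "slitflow_consistency_error")
    }
    if (sum(g(c("SCD", "THAL", "HS"), col)) != g("RHHA", col)) {
      abort(sprintf("%s: SCD + THAL + HS != RHHA", col),
            "slitflow_consistency_error")
    }
  }
  invisible(TRUE)
}
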
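#' Construct a dose x time x replicate study design
#'
#' Builds the sample sheet for a factorial irradiation experiment: every
#' combination of dose and harvest time is observed in `replicates`
#' biological replicates. The default reproduces a 3-dose (0/10/100 cGy),
#' 4-time (0/3/8/24 h), duplicate design of 24 samples, with 0 cGy acting
#' as the unirradiated control.
#'
#' Sample ordering is deterministic: doses vary slowest, then times, then
#' replicates, so the same arguments always yield the same sheet.
#'
#' @param doses Numeric vector of distinct dose levels in cGy. The smallest
#'   level is conventionally the control.
#' @param times Numeric vector of distinct harvest times in hours.
#' @param replicates Number of replicates per dose x time cell (>= 1).
#'
#' @return A data frame of class `study_design` with columns `sample_id`,
#'   `dose_cGy`, `time_h`, `replicate`, one row per sample, and attributes
#'   `doses`, `times`, `replicates`.
#' @examples
#' d <- radiation_design()
#' nrow(d)  # 24
#' @export
radiation_design <- function(doses = c(0, 10, 100), times = c(0, 3, 8, 24),
                             replicates = 2) {
  if (length(doses) < 1L || length(times) < 1L)
    stop("`doses` and `times` must be non-empty")
  if (anyDuplicated(doses)) stop("duplicate dose levels are not allowed")
  if (anyDuplicated(times)) stop("duplicate time points are not allowed")
  if (replicates < 1L) stop("`replicates` must be >= 1")

  grid <- expand.grid(replicate = seq_len(replicates), time_h = times,
                      dose_cGy = doses, KEEP.OUT.ATTRS = FALSE)
  design <- data.frame(
    sample_id = sprintf("D%s_T%s_R%d", grid$dose_cGy, grid$time_h,
                        grid$replicate),
    dose_cGy = grid$dose_cGy,
    time_h = grid$time_h,
    replicate = grid$replicate,
    stringsAsFactors = FALSE
  )
  structure(design, doses = doses, times = times, replicates = replicates,
            class = c("study_design", "data.frame"))
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Study design: %d doses x %d times x %d replicates = %d samples\n",
              length(attr(x, "doses")), length(attr(x, "times")),
              attr(x, "replicates"), nrow(x)))
  NextMethod()
}

# control = smallest dose; treated doses in ascending order
.control_dose <- function(design) min(attr(design, "doses"))
.treated_doses <- function(design) {
  d <- sort(attr(design, "doses"))
  d[d != d[1L]]
}

.check_design_matrix <- function(values, design) {
  if (ncol(values) != nrow(design))
    stop("matrix has ", ncol(values), " columns but design has ",
         nrow(design), " samples")
  invisible(TRUE)
}
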
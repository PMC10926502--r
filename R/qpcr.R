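# Real-time PCR interpretation: per-well amplification checks, the four-way
# sample call with delta-Cq confirmation, run summaries, and dilution-series
# standard curves.

#' Positive-call thresholds
#'
#' Defaults: end-RFU threshold 500 for the diagnostic channel and 250 for
#' the control channel; a Cq between 5 and 30 counts as amplification; the
#' delta-Cq cutoff confirming a sample as positive is 7 cycles.
#'
#' @param rfu_diag,rfu_ctrl end-RFU thresholds per channel.
#' @param cq_min,cq_max Cq window for a positive amplification.
#' @param delta_max maximum |control Cq - diagnostic Cq| for a confirmed
#'   positive.
#' @return list of class `call_thresholds`.
#' @export
call_thresholds <- function(rfu_diag = 500, rfu_ctrl = 250, cq_min = 5,
                            cq_max = 30, delta_max = 7) {
  stopifnot(cq_min < cq_max, rfu_diag > 0, rfu_ctrl > 0, delta_max > 0)
  structure(list(rfu_diag = rfu_diag, rfu_ctrl = rfu_ctrl, cq_min = cq_min,
                 cq_max = cq_max, delta_max = delta_max),
            class = "call_thresholds")
}

#' Delta-Cq between the control and diagnostic channels
#' @param ctrl_cq,diag_cq Cq values; both must be present.
#' @return `|ctrl_cq - diag_cq|`.
#' @export
delta_cq <- function(ctrl_cq, diag_cq) {
  if (is.null(ctrl_cq) || is.null(diag_cq) || is.na(ctrl_cq) ||
      is.na(diag_cq))
    stop("both Cq values must be present; handle no-amplification first")
  abs(ctrl_cq - diag_cq)
}

well_amplified <- function(cq, rfu, rfu_threshold, t) {
  !is.na(cq) && rfu >= rfu_threshold && cq >= t$cq_min && cq <= t$cq_max
}

#' Classify a sample from its diagnostic and control wells
#'
#' A channel is amplified-positive when its end RFU meets the channel
#' threshold and its Cq lies in the positive window. The call is:
#' \describe{
#'   \item{anomalous}{diagnostic Cq below the window while control Cq is
#'     above it (the copy-number-imbalance pattern; rerun in singleplex), or
#'     both channels amplified but delta-Cq exceeds the cutoff, or the
#'     diagnostic channel amplified without the control.}
#'   \item{positive}{both channels amplified-positive and delta-Cq within
#'     the cutoff.}
#'   \item{negative}{control amplified-positive, diagnostic not (the
#'     non-target pattern).}
#'   \item{failed}{neither channel amplified-positive (deteriorated
#'     template).}
#' }
#' Exactly one call is produced; every call carries its rule citations.
#'
#' @param diag,ctrl lists/rows with `cq` (NA = no amplification) and
#'   `end_rfu`.
#' @param t a [call_thresholds()].
#' @return list of class `sample_call`: `call`, `delta_cq` (NA unless both
#'   channels amplified), `reasons`.
#' @export
classify_sample <- function(diag, ctrl, t = call_thresholds()) {
  dcq <- diag$cq; drfu <- diag$end_rfu
  ccq <- ctrl$cq; crfu <- ctrl$end_rfu
  if (!is.na(dcq) && dcq <= 0) stop("Cq must be positive")
  if (!is.na(ccq) && ccq <= 0) stop("Cq must be positive")
  damp <- well_amplified(dcq, drfu, t$rfu_diag, t)
  camp <- well_amplified(ccq, crfu, t$rfu_ctrl, t)
  dq <- if (!is.na(dcq) && !is.na(ccq)) delta_cq(ccq, dcq) else NA_real_
  reasons <- character(0)
  if (!is.na(dcq) && dcq < t$cq_min && !is.na(ccq) && ccq > t$cq_max) {
    call <- "anomalous"
    reasons <- sprintf(
      "diagnostic Cq %.2f below window [%g,%g] with control Cq %.2f above it",
      dcq, t$cq_min, t$cq_max, ccq)
  } else if (damp && camp && dq <= t$delta_max) {
    call <- "positive"
    reasons <- sprintf(
      "both channels amplified within thresholds; delta-Cq %.2f <= %g",
      dq, t$delta_max)
  } else if (damp && camp) {
    call <- "anomalous"
    reasons <- sprintf("both channels amplified but delta-Cq %.2f > %g",
                       dq, t$delta_max)
  } else if (damp && !camp) {
    call <- "anomalous"
    reasons <- "diagnostic channel amplified without the control channel"
  } else if (!damp && camp) {
    call <- "negative"
    reasons <- "control amplified-positive, diagnostic not (non-target pattern)"
  } else {
    call <- "failed"
    reasons <- "no amplified-positive channel (template likely degraded)"
  }
  structure(list(call = call,
                 delta_cq = if (damp && camp) dq else NA_real_,
                 reasons = reasons),
            class = "sample_call")
}

#' @export
print.sample_call <- function(x, ...) {
  cat(sprintf("call: %s%s\n  %s\n", x$call,
              if (!is.na(x$delta_cq))
                sprintf(" (delta-Cq %.2f)", x$delta_cq) else "",
              paste(x$reasons, collapse = "; ")))
  invisible(x)
}

#' Classify every sample in a well table
#'
#' @param wells data.frame with columns `sample_id`, `channel`
#'   (diagnostic/control), `cq` (NA = no amplification), `end_rfu`.
#' @param t a [call_thresholds()].
#' @return data.frame: `sample_id`, `call`, `delta_cq`, `reasons`.
#' @export
classify_run <- function(wells, t = call_thresholds()) {
  req <- c("sample_id", "channel", "cq", "end_rfu")
  if (length(setdiff(req, names(wells))))
    stop("well table needs columns: ", paste(req, collapse = ", "))
  rows <- lapply(split(wells, wells$sample_id), function(w) {
    d <- w[w$channel == "diagnostic", ]
    c_ <- w[w$channel == "control", ]
    if (nrow(d) != 1 || nrow(c_) != 1)
      stop("sample ", w$sample_id[1],
           ": need exactly one diagnostic and one control well")
    cl <- classify_sample(as.list(d), as.list(c_), t)
    data.frame(sample_id = w$sample_id[1], call = cl$call,
               delta_cq = cl$delta_cq,
               reasons = paste(cl$reasons, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit a qPCR standard curve
#'
#' Least-squares line of Cq on log10(concentration); amplification efficiency
#' `E = 10^(-1/slope) - 1`; the detection floor is the lowest concentration
#' at which every replicate produced a Cq.
#'
#' @param points data.frame with columns `conc` (ng/uL, > 0) and `cq` (NA =
#'   no amplification).
#' @return list of class `standard_curve`: `slope`, `intercept`, `r`,
#'   `efficiency`, `detection_floor`, `fit` (the lm object).
#' @export
fit_standard_curve <- function(points) {
  stopifnot(all(c("conc", "cq") %in% names(points)))
  if (any(points$conc <= 0)) stop("concentrations must be positive")
  amp <- points[!is.na(points$cq), , drop = FALSE]
  if (length(unique(amp$conc)) < 3)
    stop("need at least 3 distinct concentrations with amplification")
  fit <- stats::lm(cq ~ log10(conc), data = amp)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r <- suppressWarnings(stats::cor(log10(amp$conc), amp$cq))
  floor_candidates <- vapply(split(points, points$conc),
                             function(g) all(!is.na(g$cq)), TRUE)
  concs <- as.numeric(names(floor_candidates))
  detection_floor <- if (any(floor_candidates))
    min(concs[floor_candidates]) else NA_real_
  structure(list(slope = slope, intercept = intercept, r = r,
                 efficiency = 10^(-1 / slope) - 1,
                 detection_floor = detection_floor, fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard curve: slope %.4f, intercept %.2f, r %.4f, efficiency %.1f%%\n",
    x$slope, x$intercept, x$r, 100 * x$efficiency))
  invisible(x)
}

#' Summarize a qPCR run
#'
#' Per channel: min/max/mean/SD (sample SD, n-1; a single observation
#' reports SD 0 with a flag) of Cq and end RFU over amplified wells (Cq
#' present); the call tally; and a suggested RFU threshold per channel
#' (half the minimum amplified end RFU, rounded down to the nearest 50 - a
#' conservative floor below the observed signal cloud).
#'
#' @param calls data.frame from [classify_run()] (may be NULL).
#' @param wells the well table.
#' @return list: `channel_stats` (data.frame), `call_tally` (table or NULL),
#'   `suggested_rfu` (named numeric).
#' @export
summarize_run <- function(calls, wells) {
  if (!nrow(wells)) stop("need at least one well")
  stats_one <- function(v) {
    if (!length(v)) return(c(min = NA, max = NA, mean = NA, sd = NA,
                             n = 0, single = NA))
    s <- if (length(v) > 1) stats::sd(v) else 0
    c(min = min(v), max = max(v), mean = mean(v), sd = s, n = length(v),
      single = as.numeric(length(v) == 1))
  }
  ch <- lapply(split(wells, wells$channel), function(w) {
    amp <- w[!is.na(w$cq), , drop = FALSE]
    cbind(metric = c("cq", "end_rfu"),
          as.data.frame(rbind(stats_one(amp$cq), stats_one(amp$end_rfu))))
  })
  channel_stats <- do.call(rbind, Map(function(d, nm)
    cbind(channel = nm, d), ch, names(ch)))
  rownames(channel_stats) <- NULL
  sug <- vapply(split(wells, wells$channel), function(w) {
    amp <- w$end_rfu[!is.na(w$cq)]
    if (!length(amp)) return(NA_real_)
    50 * floor(min(amp) / 2 / 50)
  }, 0)
  list(channel_stats = channel_stats,
       call_tally = if (!is.null(calls)) table(calls$call) else NULL,
       suggested_rfu = sug)
}

#' Read a qPCR well table
#'
#' CSV with columns `sample_id`, `channel`, `cq` (empty = no amplification),
#' `end_rfu`.
#' @param path CSV path.
#' @return well data.frame.
#' @export
read_qpcr_wells <- function(path) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "channel", "cq", "end_rfu")
  miss <- setdiff(req, names(w))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  w$cq <- suppressWarnings(as.numeric(w$cq))
  w$end_rfu <- as.numeric(w$end_rfu)
  bad <- setdiff(unique(w$channel), c("diagnostic", "control"))
  if (length(bad)) stop("unknown channel label(s): ",
                        paste(bad, collapse = ", "))
  w
}
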
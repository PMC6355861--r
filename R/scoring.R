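#' Score the Weekly Hassle Scale for one person-occasion
#'
#' Computes the three weekly hassle measures from the 30 item responses of
#' one participant at one occasion: `WHS_n`, the number of hassles that
#' occurred at least once (frequency >= 1); `WHS_occur`, the mean occurrence
#' frequency; and `WHS_intens`, the mean stressfulness rating of the
#' occurred hassles (0 if none occurred).
#'
#' The denominator of `WHS_occur` is configurable: `"all_items"` (default)
#' divides the summed frequencies by the full item count, so non-occurred
#' hassles contribute zeros; `"occurred_items"` averages over the occurred
#' hassles only. The default is the reading consistent with observed scale
#' means around 0.7 on the 0-4 response scale when roughly 12 of 30 hassles
#' occur.
#'
#' @param frequency integer vector of occurrence frequencies (0-4).
#' @param intensity integer vector of stressfulness ratings (0-4), `NA`
#'   where the hassle did not occur; must be absent (NA) when frequency is 0.
#' @param n_items nominal item count of the scale (denominator for
#'   `WHS_occur` under `"all_items"`).
#' @param occur_denominator `"all_items"` or `"occurred_items"`.
#' @return Named numeric vector `c(WHS_n, WHS_occur, WHS_intens)`.
#' @examples
#' f <- c(2, 1, 3, rep(0, 27)); i <- c(4, 2, 0, rep(NA, 27))
#' score_whs(f, i)  # WHS_n 3, WHS_occur 0.2, WHS_intens 2
#' @export
score_whs <- function(frequency, intensity = rep(NA_integer_, length(frequency)),
                      n_items = 30L,
                      occur_denominator = c("all_items", "occurred_items")) {
  occur_denominator <- match.arg(occur_denominator)
  if (length(frequency) > n_items) {
    stop("more than ", n_items, " WHS items supplied", call. = FALSE)
  }
  if (length(intensity) != length(frequency)) {
    stop("frequency and intensity must have equal length", call. = FALSE)
  }
  check_ordinal(frequency, "frequency")
  check_ordinal(intensity[!is.na(intensity)], "intensity")
  bad <- which(!is.na(intensity) & frequency == 0)
  if (length(bad)) {
    stop("intensity rating present for non-occurred hassle at item(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  occurred <- frequency >= 1
  whs_n <- sum(occurred)
  denom <- if (occur_denominator == "all_items") n_items else max(whs_n, 1L)
  whs_occur <- sum(frequency) / denom
  whs_intens <- if (whs_n == 0) 0 else mean(intensity[occurred], na.rm = TRUE)
  if (is.nan(whs_intens)) whs_intens <- 0
  c(WHS_n = whs_n, WHS_occur = whs_occur, WHS_intens = whs_intens)
}

check_ordinal <- function(x, what) {
  bad <- which(!(x %in% 0:4))
  if (length(bad)) {
    stop(what, " outside 0..4 at item(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

#' Score the 10-item Perceived Stress Scale
#'
#' Sum score (0-40) after reverse-coding the positively worded items
#' (response `x` becomes `4 - x`). The standard PSS-10 reverse set is items
#' 4, 5, 7 and 8.
#'
#' @param responses integer vector of 10 raw responses (0-4).
#' @param reverse_items indices of items to reverse-code.
#' @return The PSS sum score.
#' @examples
#' score_pss(rep(4, 10))  # 6*4 + 4*0 = 24
#' @export
score_pss <- function(responses, reverse_items = c(4, 5, 7, 8)) {
  if (length(responses) != 10L) {
    stop("PSS requires exactly 10 item responses, got ", length(responses),
         call. = FALSE)
  }
  check_ordinal(responses, "response")
  x <- responses
  x[reverse_items] <- 4L - x[reverse_items]
  sum(x)
}

#' Score the TICS chronic-stress screening scale
#'
#' Plain sum of the 12 Likert items (0 = never to 4 = very often),
#' range 0-48.
#' @param responses integer vector of 12 responses (0-4).
#' @return The TICS sum score.
#' @export
score_tics <- function(responses) {
  if (length(responses) != 12L) {
    stop("TICS requires exactly 12 item responses, got ", length(responses),
         call. = FALSE)
  }
  check_ordinal(responses, "response")
  sum(responses)
}

#' Score the empathy scale
#'
#' Plain sum of the 23 Likert items (0-4). Provided for completeness of the
#' instrument set; the empathy scale feeds no downstream analysis here.
#' @param responses integer vector of 23 responses (0-4).
#' @return The ES sum score.
#' @export
score_es <- function(responses) {
  if (length(responses) != 23L) {
    stop("ES requires exactly 23 item responses, got ", length(responses),
         call. = FALSE)
  }
  check_ordinal(responses, "response")
  sum(responses)
}

#' Score a full item panel
#'
#' Applies the instrument-specific scoring rules to every
#' participant x informant x instrument x occasion cell of a long-format
#' item panel (as produced by [simulate_items()] or read with
#' [read_panel()]), yielding a tidy table of scale scores.
#'
#' @param panel long-format item panel with columns `participant_id`,
#'   `informant`, `instrument` (`WHS`, `PSS`, `TICS`), `occasion_week`,
#'   `item`, `frequency`, `intensity`.
#' @param occur_denominator passed to [score_whs()].
#' @param pss_reverse_items passed to [score_pss()].
#' @param whs_items nominal WHS item count.
#' @return A data.frame with columns `participant_id`, `informant`,
#'   `measure` (`WHS_n`, `WHS_occur`, `WHS_intens`, `PSS`, `TICS`),
#'   `occasion_week`, `value`.
#' @export
score_panel <- function(panel,
                        occur_denominator = c("all_items", "occurred_items"),
                        pss_reverse_items = c(4, 5, 7, 8),
                        whs_items = 30L) {
  occur_denominator <- match.arg(occur_denominator)
  need <- c("participant_id", "informant", "instrument", "occasion_week",
            "item", "frequency")
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols)) {
    stop("panel lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"intensity" %in% names(panel)) panel$intensity <- NA_integer_
  out <- list()

  whs <- panel[panel$instrument == "WHS", ]
  if (nrow(whs)) {
    if (any(!is.na(whs$intensity) & whs$frequency == 0)) {
      stop("intensity rating present for non-occurred WHS hassle", call. = FALSE)
    }
    check_ordinal(whs$frequency, "WHS frequency")
    key <- interaction(whs$participant_id, whs$informant, whs$occasion_week,
                       drop = TRUE, lex.order = TRUE)
    occurred <- as.numeric(whs$frequency >= 1)
    n_occ <- rowsum(occurred, key)
    freq_sum <- rowsum(as.numeric(whs$frequency), key)
    int_sum <- rowsum(ifelse(is.na(whs$intensity), 0, as.numeric(whs$intensity)), key)
    denom <- if (occur_denominator == "all_items") whs_items else pmax(n_occ, 1)
    ids <- do.call(rbind, strsplit(rownames(n_occ), ".", fixed = TRUE))
    base <- data.frame(participant_id = as.integer(ids[, 1]),
                       informant = ids[, 2],
                       occasion_week = as.integer(ids[, 3]))
    out$whs_n <- cbind(base, measure = "WHS_n", value = as.numeric(n_occ))
    out$whs_occur <- cbind(base, measure = "WHS_occur",
                           value = as.numeric(freq_sum / denom))
    out$whs_int <- cbind(base, measure = "WHS_intens",
                         value = as.numeric(ifelse(n_occ == 0, 0, int_sum / pmax(n_occ, 1))))
  }

  for (inst in c("PSS", "TICS")) {
    sub <- panel[panel$instrument == inst, ]
    if (!nrow(sub)) next
    check_ordinal(sub$frequency, paste(inst, "response"))
    x <- as.numeric(sub$frequency)
    if (inst == "PSS" && length(pss_reverse_items)) {
      rev <- sub$item %in% pss_reverse_items
      x[rev] <- 4 - x[rev]
    }
    key <- interaction(sub$participant_id, sub$informant, sub$occasion_week,
                       drop = TRUE, lex.order = TRUE)
    cnt <- rowsum(rep(1, length(x)), key)
    expect <- if (inst == "PSS") 10L else 12L
    if (any(cnt != expect)) {
      stop(inst, " cells with item counts other than ", expect, " found",
           call. = FALSE)
    }
    s <- rowsum(x, key)
    ids <- do.call(rbind, strsplit(rownames(s), ".", fixed = TRUE))
    out[[inst]] <- data.frame(participant_id = as.integer(ids[, 1]),
                              informant = ids[, 2],
                              occasion_week = as.integer(ids[, 3]),
                              measure = inst, value = as.numeric(s))
  }
  scores <- do.call(rbind, out)
  rownames(scores) <- NULL
  scores <- scores[order(scores$measure, scores$informant,
                         scores$participant_id, scores$occasion_week), ]
  rownames(scores) <- NULL
  scores[, c("participant_id", "informant", "measure", "occasion_week", "value")]
}

#' Preprocess raw hair-cortisol triplicates
#'
#' For each participant: averages the assay triplicates within each 1-cm
#' segment, averages the segment means on the raw concentration scale, and
#' takes the natural log of that average (`log_hcc`). Also computes the
#' replicate coefficient of variation (sample SD / mean) of every
#' triplicate set; the median CV across all sets is attached as an
#' attribute and reported per participant.
#'
#' @param hair long data.frame with columns `participant_id`, `segment`,
#'   `replicate`, `cortisol_pg_per_mg` (all values > 0).
#' @param missing_segment `"error"` to require all three segments,
#'   `"average"` to average the available segments with a warning.
#' @param quantification_floor assay lower limit of quantification (pg/mg);
#'   values at or below it are flagged, not removed.
#' @return A data.frame with one row per participant: segment means
#'   (`seg1`-`seg3`), `hcc_avg` (raw-scale 3-segment average), `log_hcc`,
#'   `median_cv` (median replicate CV of that participant's sets, percent)
#'   and `n_below_floor`. Attribute `"median_cv"` holds the study-wide
#'   median replicate CV in percent.
#' @examples
#' h <- data.frame(participant_id = 1, segment = rep(1:3, each = 3),
#'                 replicate = rep(1:3, 3), cortisol_pg_per_mg = 4.06)
#' preprocess_hcc(h)$log_hcc  # log(4.06)
#' @export
preprocess_hcc <- function(hair, missing_segment = c("error", "average"),
                           quantification_floor = 0.1) {
  missing_segment <- match.arg(missing_segment)
  need <- c("participant_id", "segment", "replicate", "cortisol_pg_per_mg")
  missing_cols <- setdiff(need, names(hair))
  if (length(missing_cols)) {
    stop("hair data lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(hair$cortisol_pg_per_mg) | hair$cortisol_pg_per_mg <= 0)) {
    stop("nonpositive cortisol value(s) in hair data", call. = FALSE)
  }
  set_key <- interaction(hair$participant_id, hair$segment, drop = TRUE)
  set_mean <- tapply(hair$cortisol_pg_per_mg, set_key, mean)
  set_sd <- tapply(hair$cortisol_pg_per_mg, set_key, stats::sd)
  set_cv <- 100 * set_sd / set_mean
  set_pid <- tapply(hair$participant_id, set_key, `[`, 1)

  pids <- sort(unique(hair$participant_id))
  rows <- lapply(pids, function(pid) {
    sub <- hair[hair$participant_id == pid, ]
    segs <- sort(unique(sub$segment))
    if (length(segs) < 3 && missing_segment == "error") {
      stop("participant ", pid, " lacks segment(s) ",
           paste(setdiff(1:3, segs), collapse = ", "), call. = FALSE)
    }
    seg_means <- tapply(sub$cortisol_pg_per_mg, sub$segment, mean)
    full <- stats::setNames(rep(NA_real_, 3), 1:3)
    full[names(seg_means)] <- seg_means
    avg <- mean(seg_means)
    cvs <- set_cv[set_pid == pid]
    data.frame(participant_id = pid,
               seg1 = full[["1"]], seg2 = full[["2"]], seg3 = full[["3"]],
               hcc_avg = avg, log_hcc = log(avg),
               median_cv = stats::median(cvs, na.rm = TRUE),
               n_below_floor = sum(sub$cortisol_pg_per_mg <= quantification_floor))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(is.na(out$seg1) | is.na(out$seg2) | is.na(out$seg3))) {
    warning("some participants lack hair segments; averaged available segments")
  }
  attr(out, "median_cv") <- stats::median(set_cv, na.rm = TRUE)
  out
}
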
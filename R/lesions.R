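# Lesion detection and reference-diameter estimation.
#
# Reference diameters come from "normal shoulder" windows on either side of
# a narrowing: the median diameter over a window immediately proximal /
# distal to the lesion, with linear interpolation in between. The %DS
# detection rule itself is package plumbing (threshold configurable); it
# seeds stent planning, which is additionally FFR-gradient driven.

#' Reference diameter across a lesion window
#'
#' The proximal reference is the median lumen diameter over a shoulder
#' window of width `shoulder` immediately proximal to the lesion window;
#' the distal reference likewise immediately distal. Between the two ends
#' of the window the reference is linearly interpolated in arc length;
#' outside it the nearer shoulder value applies.
#'
#' @param profile a [centerline_profile()]
#' @param lesion_window numeric length-2, `(s_start, s_end)` in mm, strictly
#'   inside the segment with room for both shoulders
#' @param shoulder shoulder window width (mm), default 5
#' @return list with `d_ref_prox`, `d_ref_dist` (mm) and `reference`, the
#'   per-sample reference diameter on the profile's own grid
#' @export
reference_diameter_profile <- function(profile, lesion_window, shoulder = 5) {
  s <- profile$s_mm
  d <- 2 * profile$r_mm
  s_start <- lesion_window[1]
  s_end <- lesion_window[2]
  if (s_start >= s_end)
    stop_ffrct("lesion window must have s_start < s_end", class = "ffrct_geometry_error")
  if (s_start - shoulder < s[1] || s_end + shoulder > s[length(s)])
    stop_ffrct(paste0("lesion window (%.1f, %.1f) leaves no %.1f mm normal shoulder ",
                      "inside the segment; extend the geometry or supply reference ",
                      "diameters explicitly"), s_start, s_end, shoulder,
               class = "ffrct_geometry_error")
  prox <- d[s >= s_start - shoulder & s < s_start]
  dist <- d[s > s_end & s <= s_end + shoulder]
  if (length(prox) == 0L || length(dist) == 0L)
    stop_ffrct("shoulder windows contain no samples; resample the profile first",
               class = "ffrct_geometry_error")
  d_ref_prox <- stats::median(prox)
  d_ref_dist <- stats::median(dist)
  ref <- ifelse(s <= s_start, d_ref_prox,
                ifelse(s >= s_end, d_ref_dist,
                       d_ref_prox + (d_ref_dist - d_ref_prox) *
                         (s - s_start) / (s_end - s_start)))
  list(d_ref_prox = d_ref_prox, d_ref_dist = d_ref_dist, reference = ref)
}

# Robust "healthy lumen" envelope: iteratively refit a line through the
# samples at or above the current fit, so narrowings drop out of the fit.
healthy_envelope <- function(s, d, iters = 4L) {
  keep <- rep(TRUE, length(s))
  fit <- NULL
  for (i in seq_len(iters)) {
    if (sum(keep) < 4L) break
    fit <- stats::lm.fit(cbind(1, s[keep]), d[keep])
    pred <- cbind(1, s) %*% fit$coefficients
    keep <- d >= pred - 1e-9
  }
  if (is.null(fit)) return(rep(stats::median(d), length(s)))
  as.numeric(cbind(1, s) %*% fit$coefficients)
}

#' Detect lesions on a coronary tree
#'
#' Each segment is resampled, a robust healthy-lumen envelope is fitted,
#' and contiguous runs where percent diameter stenosis against that
#' envelope reaches `min_pct_ds` become candidate lesions. Runs separated
#' by less than `merge_gap` merge into one (serial-lesion handling). Each
#' candidate is then re-referenced against shoulder medians
#' ([reference_diameter_profile()]) and its %DS reported as
#' `100 * (1 - d_min / d_ref)` with the reference interpolated at the
#' location of the minimal lumen diameter.
#'
#' @param tree a [coronary_tree()]
#' @param min_pct_ds detection threshold, percent diameter stenosis
#'   (default 30)
#' @param merge_gap runs closer than this merge into one lesion (mm)
#' @param shoulder shoulder window width for reference diameters (mm)
#' @param ds resampling spacing (mm), must be <= 0.5
#' @return data frame of class `lesion_table` with one row per lesion:
#'   `segment_id`, `s_start`, `s_end`, `s_min`, `d_min`, `d_ref_prox`,
#'   `d_ref_dist`, `pct_ds`
#' @export
detect_lesions <- function(tree, min_pct_ds = 30, merge_gap = 5,
                           shoulder = 5, ds = 0.5) {
  if (!inherits(tree, "coronary_tree"))
    stop_ffrct("detect_lesions needs a coronary_tree", class = "ffrct_geometry_error")
  if (ds > 0.5)
    stop_ffrct("profiles must be resampled to <= 0.5 mm spacing (ds = %.2f)", ds,
               class = "ffrct_geometry_error")
  out <- list()
  for (id in names(tree$segments)) {
    prof <- resample_profile(tree$segments[[id]]$profile, ds)
    s <- prof$s_mm
    d <- 2 * prof$r_mm
    env <- healthy_envelope(s, d)
    pct <- 100 * (1 - d / env)
    hit <- pct >= min_pct_ds
    if (!any(hit)) next
    runs <- run_windows(s, hit)
    runs <- merge_windows(runs, merge_gap)
    for (w in runs) {
      # the threshold run sits inside the lesion flanks; expand to the full
      # extent (envelope stenosis below 5%) so shoulders sample normal lumen
      w <- expand_window(w, s, pct, floor_pct = 5, max_extend = 10)
      win <- clamp_window(w, s, shoulder)
      ref <- tryCatch(reference_diameter_profile(prof, win, shoulder),
                      error = function(e) NULL)
      idx <- which(s >= win[1] & s <= win[2])
      i_min <- idx[which.min(d[idx])]
      if (is.null(ref)) {
        d_ref_at_min <- env[i_min]
        d_ref_prox <- env[which.min(abs(s - win[1]))]
        d_ref_dist <- env[which.min(abs(s - win[2]))]
      } else {
        d_ref_at_min <- ref$reference[i_min]
        d_ref_prox <- ref$d_ref_prox
        d_ref_dist <- ref$d_ref_dist
      }
      out[[length(out) + 1L]] <- data.frame(
        segment_id = id, s_start = win[1], s_end = win[2], s_min = s[i_min],
        d_min = d[i_min], d_ref_prox = d_ref_prox, d_ref_dist = d_ref_dist,
        pct_ds = 100 * (1 - d[i_min] / d_ref_at_min))
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(segment_id = character(0), s_start = numeric(0), s_end = numeric(0),
               s_min = numeric(0), d_min = numeric(0), d_ref_prox = numeric(0),
               d_ref_dist = numeric(0), pct_ds = numeric(0))
  rownames(res) <- NULL
  class(res) <- c("lesion_table", "data.frame")
  res
}

run_windows <- function(s, hit) {
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  wins <- list()
  for (i in seq_along(r$values))
    if (r$values[i]) wins[[length(wins) + 1L]] <- c(s[starts[i]], s[ends[i]])
  wins
}

merge_windows <- function(wins, merge_gap) {
  if (length(wins) <= 1L) return(wins)
  wins <- wins[order(vapply(wins, `[`, 0, 1))]
  out <- list(wins[[1]])
  for (w in wins[-1]) {
    last <- out[[length(out)]]
    if (w[1] - last[2] < merge_gap) {
      out[[length(out)]] <- c(last[1], max(last[2], w[2]))
    } else out[[length(out) + 1L]] <- w
  }
  out
}

expand_window <- function(w, s, pct, floor_pct = 5, max_extend = 10) {
  i1 <- which.min(abs(s - w[1]))
  i2 <- which.min(abs(s - w[2]))
  while (i1 > 1L && pct[i1 - 1L] > floor_pct && s[i1 - 1L] >= w[1] - max_extend)
    i1 <- i1 - 1L
  while (i2 < length(s) && pct[i2 + 1L] > floor_pct &&
         s[i2 + 1L] <= w[2] + max_extend)
    i2 <- i2 + 1L
  c(s[i1], s[i2])
}

clamp_window <- function(w, s, shoulder) {
  lo <- s[1] + shoulder
  hi <- s[length(s)] - shoulder
  c(max(w[1], min(lo, w[2])), min(w[2], max(hi, w[1])))
}

# Per-sample reference diameter for a segment given its detected lesions;
# used by the CSV export. Falls back to the envelope where no lesion is.
segment_reference <- function(prof, lesions) {
  s <- prof$s_mm
  d <- 2 * prof$r_mm
  ref <- healthy_envelope(s, d)
  if (nrow(lesions)) {
    for (i in seq_len(nrow(lesions))) {
      r <- tryCatch(
        reference_diameter_profile(prof, c(lesions$s_start[i], lesions$s_end[i])),
        error = function(e) NULL)
      if (!is.null(r)) {
        inside <- s >= lesions$s_start[i] & s <= lesions$s_end[i]
        ref[inside] <- r$reference[inside]
      }
    }
  }
  ref
}
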
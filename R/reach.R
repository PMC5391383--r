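# The maximum tail-reach statistic: per frame, the largest distance from
# the anchor CA (P43 for the H3 tail) to any CA on its N-terminal side.

#' Maximum reach of one frame
#'
#' @param coords n_atoms x 3 coordinate matrix for one frame.
#' @param topology Atom tibble describing the atoms.
#' @param anchor_res Residue number of the anchor CA (default 43, i.e. P43
#'   of the H3 tail). Only residues strictly N-terminal of the anchor
#'   (`res_seq < anchor_res`) are scanned.
#' @return Maximum anchor-to-CA distance, Angstrom.
#' @export
max_reach_frame <- function(coords, topology, anchor_res = 43) {
  ca <- which(topology$name == "CA")
  anchor <- ca[topology$res_seq[ca] == anchor_res]
  if (length(anchor) != 1) {
    stop("anchor CA for residue ", anchor_res, " not found", call. = FALSE)
  }
  nterm <- ca[topology$res_seq[ca] < anchor_res]
  if (length(nterm) == 0) {
    stop("no CA atoms N-terminal of residue ", anchor_res, call. = FALSE)
  }
  d <- sweep(coords[nterm, , drop = FALSE], 2, coords[anchor, ])
  max(sqrt(rowSums(d^2)))
}

#' Per-frame reach series of a trajectory
#'
#' @param traj A `tail_trajectory`.
#' @param anchor_res Anchor residue number (see [max_reach_frame()]).
#' @return A tibble with columns `frame`, `time_ps`, `reach` and an
#'   `anchor_res` attribute.
#' @export
reach_series <- function(traj, anchor_res = 43) {
  nf <- n_frames(traj)
  vals <- vapply(seq_len(nf), function(i) {
    max_reach_frame(frame_coords(traj, i), traj$topology, anchor_res)
  }, numeric(1))
  out <- tibble::tibble(
    frame = seq_len(nf),
    time_ps = (seq_len(nf) - 1) * traj$dt,
    reach = vals
  )
  attr(out, "anchor_res") <- anchor_res
  out
}

#' Quartile summary of a reach series
#'
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7); the same convention fixes the inner/outer
#' radii of the chromatin reach shells, which inherit Q1 and Q3 from this
#' summary. Whiskers follow either the Tukey 1.5 IQR rule or the sample
#' min/max.
#'
#' @param r A reach series tibble from [reach_series()], or any data frame
#'   with a `reach` column.
#' @param whiskers `"tukey"` (1.5 IQR, default) or `"minmax"`.
#' @return A one-row tibble with `n`, `q1`, `median`, `q3`, `whisker_low`,
#'   `whisker_high`, `n_outliers`.
#' @export
summarize_reach <- function(r, whiskers = c("tukey", "minmax")) {
  whiskers <- match.arg(whiskers)
  v <- r$reach
  if (length(v) == 0) stop("empty reach series", call. = FALSE)
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  if (whiskers == "tukey") {
    iqr <- q[3] - q[1]
    lo_lim <- q[1] - 1.5 * iqr
    hi_lim <- q[3] + 1.5 * iqr
    wl <- min(v[v >= lo_lim])
    wh <- max(v[v <= hi_lim])
    n_out <- sum(v < lo_lim | v > hi_lim)
  } else {
    wl <- min(v)
    wh <- max(v)
    n_out <- 0L
  }
  tibble::tibble(
    n = length(v), q1 = q[1], median = q[2], q3 = q[3],
    whisker_low = wl, whisker_high = wh, n_outliers = n_out
  )
}

#' Welch two-sample comparison of reach series
#'
#' Unpaired t-test with the Welch correction for unequal variances, at a
#' 95% confidence interval, two-sided. Accepts reach-series tibbles or bare
#' numeric vectors. When both samples are constant and equal, the
#' convention t = 0, p = 1 is returned.
#'
#' @param a,b Reach series (data frames with a `reach` column) or numeric
#'   vectors, each of length >= 2.
#' @param conf_level Confidence level of the interval.
#' @return A one-row tibble with `estimate` (mean of `a` minus mean of
#'   `b`), `t`, `df`, `p_value`, `conf_low`, `conf_high`, `mean_a`,
#'   `mean_b`, `n_a`, `n_b`.
#' @export
welch_test <- function(a, b, conf_level = 0.95) {
  xa <- if (is.data.frame(a)) a$reach else as.numeric(a)
  xb <- if (is.data.frame(b)) b$reach else as.numeric(b)
  if (length(xa) < 2 || length(xb) < 2) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  if (stats::var(xa) == 0 && stats::var(xb) == 0) {
    if (mean(xa) == mean(xb)) {
      return(tibble::tibble(
        estimate = 0, t = 0, df = length(xa) + length(xb) - 2, p_value = 1,
        conf_low = 0, conf_high = 0,
        mean_a = mean(xa), mean_b = mean(xb),
        n_a = length(xa), n_b = length(xb)
      ))
    }
    stop("both samples are constant with different means; t is undefined",
      call. = FALSE
    )
  }
  tt <- stats::t.test(xa, xb, var.equal = FALSE, conf.level = conf_level)
  tibble::tibble(
    estimate = unname(tt$estimate[1] - tt$estimate[2]),
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    conf_low = tt$conf.int[1],
    conf_high = tt$conf.int[2],
    mean_a = unname(tt$estimate[1]),
    mean_b = unname(tt$estimate[2]),
    n_a = length(xa),
    n_b = length(xb)
  )
}
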
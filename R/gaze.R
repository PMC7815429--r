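#' Gaze metric configuration
#'
#' @param d0 smallest normalized distance treated as a meaningfully
#'   different focus of gaze (kernel cap); default 0.01, i.e. 1% of video
#'   height.
#' @param minObservations minimum number of in-frame gaze observations for
#'   a frame's consistency/typicality to be defined (default 5).
#' @param frameHalfWidth,frameHalfHeight half-extents of the in-frame
#'   rectangle in normalized units (defaults 0.716 and 0.550: the 610x458
#'   video footprint plus a 0.05 buffer on each side).
#' @return list of class "GazeMetricConfig"
#' @export
gazeMetricConfig <- function(d0 = 0.01, minObservations = 5,
                             frameHalfWidth = 0.716,
                             frameHalfHeight = 0.550) {
  stopifnot(d0 > 0, minObservations >= 2,
            frameHalfWidth > 0, frameHalfHeight > 0)
  structure(list(d0 = d0, minObservations = as.integer(minObservations),
                 frameHalfWidth = frameHalfWidth,
                 frameHalfHeight = frameHalfHeight),
            class = "GazeMetricConfig")
}

#' In-frame bounds implied by a video geometry
#'
#' Normalized coordinates put the origin at the video centre with the video
#' height as 1 unit. The in-frame rectangle is the video footprint plus a
#' buffer on each side.
#'
#' @param widthPx,heightPx video resolution in pixels (defaults 610 x 458)
#' @param buffer buffer on each side in normalized units (default 0.05)
#' @return named numeric: \code{halfWidth}, \code{halfHeight}
#' @export
inFrameBounds <- function(widthPx = 610, heightPx = 458, buffer = 0.05) {
  c(halfWidth = widthPx / heightPx / 2 + buffer,
    halfHeight = 0.5 + buffer)
}

#' Convert the d0 kernel cap to video pixels
#'
#' @param d0 normalized distance (default 0.01)
#' @param heightPx video height in pixels (default 458)
#' @return distance in pixels
#' @export
d0Pixels <- function(d0 = 0.01, heightPx = 458) d0 * heightPx

#' Downsample and normalize a raw gaze trace to per-frame gaze focus
#'
#' Boxcar-averages the 1000 Hz monitor-pixel gaze signal to one sample per
#' displayed video frame, centring each boxcar window on the frame's draw
#' time (so the phase delay between frames and window centres is minimal),
#' and rescales to normalized video coordinates (video height = 1 unit,
#' origin at the video centre, x rightward, y downward).
#'
#' @param raw data.frame with columns \code{t_ms} (milliseconds since
#'   presentation onset, nominally 1 kHz), \code{x_px}, \code{y_px}
#'   (monitor pixels; NA during signal loss)
#' @param geometry list with \code{video_px} = c(width, height),
#'   \code{origin_px} = c(x, y) of the video's top-left corner on the
#'   monitor, \code{fps} (default 30) and \code{n_frames} displayed;
#'   optionally \code{frame_times_ms}, the draw time of each frame
#'   (defaults to the frame display-interval midpoints).
#' @param config a [gazeMetricConfig()]
#' @return data.frame: \code{frame} (0-based), \code{x}, \code{y}
#'   (normalized; NA when the raw trace has no usable samples in the
#'   frame's boxcar window), \code{in_frame} (logical, NA when missing)
#' @export
downsampleAndNormalize <- function(raw, geometry,
                                   config = gazeMetricConfig()) {
  stopifnot(all(c("t_ms", "x_px", "y_px") %in% names(raw)))
  fps <- if (is.null(geometry$fps)) 30 else geometry$fps
  nf <- geometry$n_frames
  stopifnot(!is.null(nf), !is.null(geometry$video_px),
            !is.null(geometry$origin_px))
  frameTimes <- if (!is.null(geometry$frame_times_ms)) geometry$frame_times_ms
                else (seq_len(nf) - 0.5) * 1000 / fps
  halfWin <- 1000 / fps / 2
  ok <- !is.na(raw$x_px) & !is.na(raw$y_px)
  t <- raw$t_ms[ok]; xr <- raw$x_px[ok]; yr <- raw$y_px[ok]
  win <- findInterval(t, c(frameTimes - halfWin,
                           frameTimes[nf] + halfWin))
  # samples sit in frame f's window when win == f and t < frameTimes[f]+halfWin
  inAny <- win >= 1L & win <= nf & t < frameTimes[pmin(win, nf)] + halfWin
  xm <- rep(NA_real_, nf); ym <- rep(NA_real_, nf)
  if (any(inAny)) {
    g <- win[inAny]
    xs <- vapply(split(xr[inAny], g), mean, numeric(1))
    ys <- vapply(split(yr[inAny], g), mean, numeric(1))
    idx <- as.integer(names(xs))
    xm[idx] <- xs; ym[idx] <- ys
  }
  w <- geometry$video_px[1]; h <- geometry$video_px[2]
  cx <- geometry$origin_px[1] + w / 2
  cy <- geometry$origin_px[2] + h / 2
  x <- (xm - cx) / h
  y <- (ym - cy) / h
  data.frame(frame = seq_len(nf) - 1L, x = x, y = y,
             in_frame = flagInFrame(x, y, config))
}

#' Flag whether a normalized gaze focus lies in frame
#'
#' In-frame means inside the closed rectangle \code{|x| <= halfWidth},
#' \code{|y| <= halfHeight} (boundaries inclusive).
#'
#' @param x,y normalized coordinates (vectorized)
#' @param config a [gazeMetricConfig()]
#' @return logical vector (NA where coordinates are NA)
#' @export
flagInFrame <- function(x, y, config = gazeMetricConfig()) {
  abs(x) <= config$frameHalfWidth & abs(y) <= config$frameHalfHeight
}

#' Gaze consistency of a set of gaze foci
#'
#' Capped inverse-distance pairwise statistic
#' \deqn{g = \frac{2 d_0}{n(n-1)} \sum_i \sum_{j<i}
#'       \frac{1}{\max(\lVert x_i - x_j \rVert, d_0)}}
#' analogous to the potential energy of a cloud of mutually repulsive
#' particles with the interaction capped below distance \code{d0}. Equals 1
#' when all foci fall within a disc of diameter \code{d0} and decreases
#' toward 0 as foci disperse; a single tight cluster scores above two
#' clusters, which score above a diffuse cloud.
#'
#' @param x,y coordinates of the n foci (n >= 2)
#' @param d0 the kernel cap distance
#' @return g in (0, 1], or NA when fewer than 2 points are supplied
#' @export
gazeConsistency <- function(x, y, d0 = 0.01) {
  stopifnot(length(x) == length(y), d0 > 0)
  n <- length(x)
  if (n < 2L) return(NA_real_)
  d <- stats::dist(cbind(x, y))
  2 * d0 / (n * (n - 1)) * sum(1 / pmax(d, d0))
}

#' Gaze typicality of each focus within a set
#'
#' Per-observation analogue of [gazeConsistency()]:
#' \deqn{\tau_i = \frac{d_0}{n-1} \sum_{j \ne i}
#'       \frac{1}{\max(\lVert x_i - x_j \rVert, d_0)}}
#' High when an observation lies near the positions that typically attract
#' gaze on that frame, low when it is far from the other observations.
#'
#' @param x,y coordinates of the n foci (n >= 2)
#' @param d0 the kernel cap distance
#' @return numeric vector of tau_i in (0, 1], one per focus; all NA when
#'   fewer than 2 points are supplied
#' @export
gazeTypicality <- function(x, y, d0 = 0.01) {
  stopifnot(length(x) == length(y), d0 > 0)
  n <- length(x)
  if (n < 2L) return(rep(NA_real_, n))
  dm <- as.matrix(stats::dist(cbind(x, y)))
  diag(dm) <- Inf
  unname(d0 / (n - 1) * rowSums(1 / pmax(dm, d0)))
}

#' Aggregate gaze focus traces per video frame
#'
#' Pools in-frame gaze foci across all viewings of each video frame and
#' computes, per frame: the proportion of gaze onscreen, gaze consistency
#' (when at least \code{minObservations} in-frame foci exist), and, per
#' viewing, the gaze typicality of each in-frame focus (NA for offscreen or
#' missing foci, and on frames below the observation threshold).
#'
#' @param traces data.frame with columns \code{presentation_id},
#'   \code{video_id}, \code{frame}, \code{x}, \code{y}, \code{in_frame}
#'   (one row per displayed frame per viewing; x/y NA for missing samples)
#' @param config a [gazeMetricConfig()]
#' @return list with \code{frames} (video_id, frame, n_total, n_inframe,
#'   proportion_onscreen, consistency) and \code{views} (the input rows
#'   plus \code{typicality} and \code{gaze_offscreen})
#' @export
aggregateFrameGaze <- function(traces, config = gazeMetricConfig()) {
  req <- c("presentation_id", "video_id", "frame", "x", "y", "in_frame")
  missing <- setdiff(req, names(traces))
  if (length(missing))
    stop("trace table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(traces[, c("presentation_id", "frame")]))
    stop("duplicate (presentation_id, frame) rows in gaze traces")
  key <- interaction(traces$video_id, traces$frame, drop = TRUE)
  idxByFrame <- split(seq_len(nrow(traces)), key)
  frames <- do.call(rbind, lapply(idxByFrame, function(idx) {
    obs <- !is.na(traces$x[idx])
    inf <- which(obs & traces$in_frame[idx])
    g <- if (length(inf) >= config$minObservations)
      gazeConsistency(traces$x[idx][inf], traces$y[idx][inf], config$d0)
    else NA_real_
    data.frame(video_id = traces$video_id[idx[1L]],
               frame = traces$frame[idx[1L]],
               n_total = sum(obs), n_inframe = length(inf),
               proportion_onscreen = if (sum(obs)) length(inf) / sum(obs)
                                     else NA_real_,
               consistency = g)
  }))
  rownames(frames) <- NULL
  frames <- frames[order(frames$video_id, frames$frame), , drop = FALSE]

  typ <- rep(NA_real_, nrow(traces))
  for (idx in idxByFrame) {
    inf <- idx[!is.na(traces$x[idx]) & traces$in_frame[idx]]
    if (length(inf) >= config$minObservations) {
      typ[inf] <- gazeTypicality(traces$x[inf], traces$y[inf], config$d0)
    }
  }
  views <- traces
  views$typicality <- typ
  views$gaze_offscreen <- ifelse(is.na(traces$in_frame), NA,
                                 as.integer(!traces$in_frame))
  list(frames = frames, views = views)
}
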
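# ChIP-seq peak calling on per-position coverage tracks. Processing order:
# raw depth -> log2(depth + 1) -> 50-bp rolling average -> subtract the
# identically processed nonspecific (background) track -> subtract the
# baseline (histogram mode across all genomic positions) -> call local maxima
# at least 3 sigma above zero, with sigma the robust MAD scale of the final
# track. Circular contigs wrap windows.

#' Construct a coverage track
#'
#' One value per genome position (0-based), tagged with the processing stage.
#'
#' @param values Numeric vector, one value per position.
#' @param contig Contig id.
#' @param circular Logical; windows wrap around the origin.
#' @param stage One of `"raw"`, `"log2"`, `"smoothed"`, `"bg_subtracted"`,
#'   `"baseline_subtracted"`.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values, contig = "genome", circular = TRUE,
                           stage = "raw") {
  stages <- c("raw", "log2", "smoothed", "bg_subtracted", "baseline_subtracted")
  stage <- match.arg(stage, stages)
  if (length(values) == 0) stop("a coverage track needs length > 0")
  if (stage == "raw" && any(values < 0)) stop("raw depths must be >= 0")
  structure(list(values = as.numeric(values), contig = contig,
                 circular = isTRUE(circular), stage = stage),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s: %d bp, %s, stage=%s\n", x$contig,
              length(x$values), if (x$circular) "circular" else "linear",
              x$stage))
  invisible(x)
}

#' Peak calling parameters
#'
#' @param window_bp Rolling-average and local-maximum window width (bp).
#' @param sigma_multiplier Calling threshold in units of the robust scale
#'   estimate (peaks must be at least this many sigma above zero).
#' @param log2_pseudocount Added to depth before log2 so zero depth maps to
#'   zero signal.
#' @param mode_bin_width Histogram bin width (log2 units) used for the
#'   baseline mode.
#' @param min_peak_separation_bp Minimum distance between retained summits;
#'   defaults to `window_bp`.
#' @return An object of class `peak_params`.
#' @export
peak_params <- function(window_bp = 50, sigma_multiplier = 3,
                        log2_pseudocount = 1, mode_bin_width = 0.1,
                        min_peak_separation_bp = window_bp) {
  if (window_bp < 1) stop("window_bp must be >= 1")
  if (sigma_multiplier <= 0) stop("sigma_multiplier must be > 0")
  if (mode_bin_width <= 0) stop("mode_bin_width must be > 0")
  structure(list(window_bp = as.integer(window_bp),
                 sigma_multiplier = sigma_multiplier,
                 log2_pseudocount = log2_pseudocount,
                 mode_bin_width = mode_bin_width,
                 min_peak_separation_bp = as.integer(min_peak_separation_bp)),
            class = "peak_params")
}

#' Per-position depth from fragment intervals
#'
#' Pileup: the value at position p is the number of fragments overlapping p.
#' Fragments use 0-based half-open coordinates; on circular contigs fragments
#' may wrap past the origin.
#'
#' @param fragments `data.frame` with columns `start`, `end` (0-based
#'   half-open).
#' @param genome_length Contig length (bp).
#' @param circular Logical; allow fragments to wrap.
#' @param contig Contig id for the returned track.
#' @return A raw [coverage_track()].
#' @export
depth_from_fragments <- function(fragments, genome_length, circular = TRUE,
                                 contig = "genome") {
  L <- as.integer(genome_length)
  s <- as.integer(fragments$start)
  e <- as.integer(fragments$end)
  if (any(s < 0)) stop("fragment coordinates must be non-negative")
  if (any(e <= s)) stop("fragments must have end > start")
  if (any(s >= L)) stop("fragment starts must lie within the genome")
  if (!circular && any(e > L)) {
    stop("fragment extends past the end of a linear contig")
  }
  wrap <- e > L
  if (any(wrap)) {  # split wrapping fragments at the origin
    s <- c(s[!wrap], s[wrap], rep(0L, sum(wrap)))
    e <- c(e[!wrap], rep(L, sum(wrap)), e[wrap] - L)
  }
  delta <- tabulate(s + 1L, nbins = L) - tabulate(e + 1L, nbins = L)
  coverage_track(cumsum(delta), contig = contig, circular = circular,
                 stage = "raw")
}

# Centered rolling mean; window covers offsets -floor(w/2) .. w-1-floor(w/2).
# Circular tracks wrap; linear tracks truncate the window at the edges.
roll_mean <- function(x, w, circular) {
  L <- length(x)
  if (w > L) stop("window is larger than the genome")
  if (w == 1) return(x)
  left <- w %/% 2L
  right <- w - 1L - left
  if (circular) {
    xp <- c(x[(L - left + 1L):L], x, x[1:right])
    cs <- c(0, cumsum(xp))
    (cs[seq_len(L) + w] - cs[seq_len(L)]) / w
  } else {
    cs <- c(0, cumsum(x))
    i <- seq_len(L)
    lo <- pmax(1L, i - left)
    hi <- pmin(L, i + right)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
}

#' Log2-transform and smooth a raw depth track
#'
#' `log2(depth + pseudocount)` followed by a centered rolling average over a
#' `window_bp`-wide window.
#'
#' @param track A raw [coverage_track()].
#' @param params [peak_params()].
#' @return A smoothed [coverage_track()].
#' @export
log2_smooth <- function(track, params = peak_params()) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$stage != "raw") stop("log2_smooth() expects a raw track")
  x <- log2(track$values + params$log2_pseudocount)
  coverage_track(roll_mean(x, params$window_bp, track$circular),
                 contig = track$contig, circular = track$circular,
                 stage = "smoothed")
}

#' Subtract the background (nonspecific) track
#'
#' Position-wise difference between two identically processed tracks.
#'
#' @param target,background Smoothed [coverage_track()]s over the same genome.
#' @return A `bg_subtracted` [coverage_track()].
#' @export
subtract_background <- function(target, background) {
  stopifnot(inherits(target, "coverage_track"),
            inherits(background, "coverage_track"))
  if (length(target$values) != length(background$values)) {
    stop("target and background tracks differ in length")
  }
  if (target$stage != background$stage) {
    stop("target and background must be at the same processing stage")
  }
  coverage_track(target$values - background$values, contig = target$contig,
                 circular = target$circular, stage = "bg_subtracted")
}

#' Baseline as the histogram mode of a processed track
#'
#' The center of the most populated histogram bin of width `mode_bin_width`
#' (bins centered on multiples of the bin width); ties break toward the lower
#' bin.
#'
#' @param track A processed [coverage_track()].
#' @param params [peak_params()].
#' @return Scalar baseline value.
#' @export
mode_baseline <- function(track, params = peak_params()) {
  stopifnot(inherits(track, "coverage_track"))
  bw <- params$mode_bin_width
  bin <- floor(track$values / bw + 0.5)  # bin k covers [k*bw - bw/2, k*bw + bw/2)
  counts <- table(bin)
  winners <- as.numeric(names(counts)[counts == max(counts)])
  min(winners) * bw
}

#' Subtract a scalar baseline from a track
#'
#' @param track A `bg_subtracted` [coverage_track()].
#' @param baseline Scalar, typically from [mode_baseline()].
#' @return A `baseline_subtracted` [coverage_track()].
#' @export
subtract_baseline <- function(track, baseline) {
  stopifnot(inherits(track, "coverage_track"), is.numeric(baseline),
            length(baseline) == 1)
  coverage_track(track$values - baseline, contig = track$contig,
                 circular = track$circular, stage = "baseline_subtracted")
}

#' Robust scale estimate of a baseline-subtracted track
#'
#' `sigma = 1.4826 * median(|v - median(v)|)` over all positions: a robust
#' alternative to the standard deviation, insensitive to the peaks themselves.
#'
#' @param track A baseline-subtracted [coverage_track()].
#' @return Scalar sigma estimate; 0 (with a warning) for a constant track.
#' @export
estimate_track_sigma <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  s <- stats::mad(track$values)
  if (s == 0) warning("degenerate constant track: sigma estimate is 0")
  s
}

#' Call peaks as 3-sigma local maxima
#'
#' A position is a candidate summit iff its value equals the maximum over the
#' centered `window_bp` window and is at least `sigma_multiplier * sigma`.
#' Candidates are then pruned greedily: the highest summit wins (leftmost on
#' exact ties) and any lower candidate within `min_peak_separation_bp` of a
#' retained summit is dropped.
#'
#' @param track A baseline-subtracted [coverage_track()].
#' @param sigma Scale estimate from [estimate_track_sigma()]; must be > 0.
#' @param params [peak_params()].
#' @return `data.frame` `contig`, `summit` (0-based), `intensity`,
#'   `sigma_score`, ordered by position.
#' @export
call_peaks <- function(track, sigma, params = peak_params()) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$stage != "baseline_subtracted") {
    stop("call_peaks() expects a baseline-subtracted track")
  }
  if (!is.numeric(sigma) || sigma <= 0) {
    stop("sigma must be > 0; peak calling refuses to run on a degenerate track")
  }
  v <- track$values
  L <- length(v)
  w <- params$window_bp
  left <- w %/% 2L
  right <- w - 1L - left
  thr <- params$sigma_multiplier * sigma

  cand <- which(v >= thr)
  is_max <- vapply(cand, function(p) {
    idx <- (p - 1L - left):(p - 1L + right)          # 0-based neighbours
    idx <- if (track$circular) idx %% L else idx[idx >= 0L & idx < L]
    v[p] >= max(v[idx + 1L])
  }, logical(1))
  cand <- cand[is_max]
  if (length(cand) == 0) {
    return(data.frame(contig = character(), summit = integer(),
                      intensity = numeric(), sigma_score = numeric()))
  }

  ord <- cand[order(-v[cand], cand)]                 # highest first, leftmost ties
  kept <- integer(0)
  for (p in ord) {
    if (length(kept) == 0 ||
        all(wrap_distance(p, kept, L, track$circular) >=
            params$min_peak_separation_bp)) {
      kept <- c(kept, p)
    }
  }
  kept <- sort(kept)
  data.frame(contig = track$contig, summit = kept - 1L,
             intensity = v[kept], sigma_score = v[kept] / sigma,
             stringsAsFactors = FALSE)
}

#' Run the full peak-calling chain on raw target and control tracks
#'
#' Convenience wrapper applying, in order: [log2_smooth()] to both tracks,
#' [subtract_background()], [mode_baseline()]/[subtract_baseline()],
#' [estimate_track_sigma()] and [call_peaks()].
#'
#' @param target,control Raw [coverage_track()]s (target and nonspecific
#'   pulldown).
#' @param params [peak_params()].
#' @return A list: `peaks` (data.frame), `sigma`, `baseline`, and `track`
#'   (the final baseline-subtracted track).
#' @export
chip_peak_pipeline <- function(target, control, params = peak_params()) {
  sm_t <- log2_smooth(target, params)
  sm_c <- log2_smooth(control, params)
  bg <- subtract_background(sm_t, sm_c)
  baseline <- mode_baseline(bg, params)
  final <- subtract_baseline(bg, baseline)
  sigma <- estimate_track_sigma(final)
  list(peaks = call_peaks(final, sigma, params), sigma = sigma,
       baseline = baseline, track = final)
}
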
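#' Modal bin depth
#'
#' Mode of the integer-rounded per-bin depths, the normalization constant of
#' the copy-number analysis. If the raw mode is zero (possible only on
#' degenerate tracks) the mode of the positive depths is used; an all-zero
#' track is an error.
#'
#' @param depths numeric vector of per-bin depths.
#' @return The modal depth (> 0).
#' @export
modal_depth <- function(depths) {
  if (!length(depths) || all(depths == 0)) stop("all-zero coverage track")
  r <- round(depths)
  tab <- tabulate(r + 1L)
  m <- which.max(tab) - 1L
  if (m == 0L) {
    pos <- r[r > 0]
    tab <- tabulate(pos)
    m <- which.max(tab)
  }
  as.numeric(m)
}

#' Normalized log2 coverage per bin
#'
#' `log2((depth + pseudocount) / modal)` for both samples, with the usable
#' flag from the germline track: a bin is usable when its germline depth lies
#' within `[0.1, 10]` times the germline modal depth, which removes
#' repeat-dominated or unsequenceable regions.
#'
#' @param track a paired `coverage_track` (columns `germline`, `tumor`).
#' @param modal_germline,modal_tumor modal depths; computed from the track
#'   when missing.
#' @param pseudocount added to depths before the log (default 0.5) so
#'   homozygous-deletion bins stay defined.
#' @return The track with `g_norm`, `t_norm` and `usable` columns; modal
#'   depths kept as attributes.
#' @export
normalized_log2 <- function(track, modal_germline = NULL, modal_tumor = NULL,
                            pseudocount = 0.5) {
  out <- as.data.table(track)
  if (is.null(modal_germline)) modal_germline <- modal_depth(out$germline)
  if (is.null(modal_tumor)) modal_tumor <- modal_depth(out$tumor)
  if (modal_germline <= 0 || modal_tumor <= 0) stop("modal depth must be positive")
  out[, `:=`(g_norm = log2((germline + pseudocount) / modal_germline),
             t_norm = log2((tumor + pseudocount) / modal_tumor),
             usable = germline >= 0.1 * modal_germline &
               germline <= 10 * modal_germline)]
  setattr(out, "bin_size", attr(track, "bin_size"))
  setattr(out, "modal_germline", modal_germline)
  setattr(out, "modal_tumor", modal_tumor)
  out[]
}

#' Sliding-window tumor minus germline normalized-coverage difference
#'
#' Windows of `window_bp` slide by one bin; the window value is the mean of
#' `t_norm - g_norm` over the usable bins inside. Windows with fewer than
#' `min_usable_frac` of their bins usable are emitted as missing (`NA`).
#'
#' @param normtab output of [normalized_log2()].
#' @param window_bp window size in bp (default 2000).
#' @param min_usable_frac minimum usable-bin fraction (default 0.5).
#' @return `data.table(contig, start, value, n_usable)`, one row per window
#'   position; attribute `window_bp`.
#' @export
windowed_difference <- function(normtab, window_bp = 2000L,
                                min_usable_frac = 0.5) {
  bin_size <- attr(normtab, "bin_size") %||% 100L
  w <- as.integer(window_bp / bin_size)
  if (w < 1) stop("window smaller than one bin")
  out <- lapply(split(as.data.table(normtab), by = "contig", sorted = TRUE),
                function(z) {
    setorder(z, start)
    d <- z$t_norm - z$g_norm
    d[!z$usable] <- 0
    u <- as.integer(z$usable)
    nb <- nrow(z)
    if (nb < w) return(NULL)
    cs <- cumsum(c(0, d)); cu <- cumsum(c(0, u))
    i <- seq_len(nb - w + 1L)
    nuse <- cu[i + w] - cu[i]
    val <- fifelse(nuse >= min_usable_frac * w,
                   (cs[i + w] - cs[i]) / nuse, NA_real_)
    data.table(contig = z$contig[1], start = z$start[i],
               value = val, n_usable = nuse)
  })
  out <- rbindlist(Filter(Negate(is.null), out))
  setattr(out, "window_bp", as.integer(window_bp))
  setattr(out, "bin_size", bin_size)
  out[]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Zygosity state thresholds for segment classification
#'
#' Derived from purity-0.6 mixture expectations on the log2 difference scale:
#' a hemizygous loss sits near `log2(0.7) = -0.515`, a homozygous loss near
#' `log2(0.4) = -1.32`, a single-copy gain near `log2(1.3) = 0.378`.
#'
#' @param homozygous_loss,hemizygous_loss,gain,amplified boundaries on the
#'   mean windowed log2 difference.
#' @return Named list.
#' @export
state_thresholds <- function(homozygous_loss = -1.0, hemizygous_loss = -0.4,
                             gain = 0.32, amplified = 1.0) {
  list(homozygous_loss = homozygous_loss, hemizygous_loss = hemizygous_loss,
       gain = gain, amplified = amplified)
}

#' Flag departing windows and merge them into copy-number segments
#'
#' Windows whose absolute value exceeds `departure` are flagged; maximal runs
#' of consecutive same-sign flagged windows — tolerating up to
#' `gap_tolerance` missing windows inside a run — become segments. Runs are
#' split where the windowed value crosses the homozygous-loss (negative runs)
#' or amplification (positive runs) boundary for at least `min_state_run`
#' consecutive windows, so a focal homozygous loss nested in a broader
#' hemizygous deletion is reported as its own segment. Segment means are
#' recomputed over the member bins.
#'
#' @param windows output of [windowed_difference()].
#' @param normtab the matching [normalized_log2()] table (for bin-level
#'   means).
#' @param departure flag threshold on the baseline-adjusted `|value|`
#'   (default 0.75).
#' @param gap_tolerance missing windows tolerated inside a run (default 2).
#' @param thresholds a [state_thresholds()] list.
#' @param min_state_run minimum windows for a state sub-run; defaults to the
#'   number of bins per window.
#' @param baseline `"auto"` (the mode of the windowed-difference density,
#'   estimating the copy-neutral level when aberrant segments pull the
#'   modal-depth normalization off center) or a numeric offset (0 disables).
#' @param min_windows minimum flagged windows supporting a segment
#'   (default 5); isolated noise windows are discarded.
#' @return `data.table` of segments: `contig`, `start`, `end`, `mean`
#'   (baseline-adjusted bin-level mean), `state`, `n_bins`, `n_windows`;
#'   disjoint and sorted, baseline recorded as an attribute.
#' @export
flag_and_segment <- function(windows, normtab, departure = 0.75,
                             gap_tolerance = 2L,
                             thresholds = state_thresholds(),
                             min_state_run = NULL, baseline = "auto",
                             min_windows = 5L) {
  window_bp <- attr(windows, "window_bp") %||% 2000L
  bin_size <- attr(windows, "bin_size") %||% 100L
  if (is.null(min_state_run)) min_state_run <- as.integer(window_bp / bin_size)
  if (identical(baseline, "auto")) baseline <- .density_mode(windows$value)
  norm <- as.data.table(normtab)
  empty <- data.table(contig = character(), start = integer(), end = integer(),
                      mean = numeric(), state = character(),
                      n_bins = integer(), n_windows = integer())
  segs <- list(empty)
  for (z in split(as.data.table(windows), by = "contig", sorted = TRUE)) {
    setorder(z, start)
    v <- z$value - baseline
    code <- integer(nrow(z))            # 0 break, 9 missing, +-1 flagged
    code[is.na(v)] <- 9L
    code[!is.na(v) & v > departure] <- 1L
    code[!is.na(v) & v < -departure] <- -1L
    runs <- .flag_runs(code, gap_tolerance)
    for (rn in runs) {
      idx <- rn$from:rn$to
      idx <- idx[code[idx] == rn$sign]  # member (non-missing) windows
      if (length(idx) < min_windows) next
      sub <- .state_split(v[idx], rn$sign, thresholds, min_state_run)
      for (s in sub) {
        m_idx <- idx[s$from:s$to]
        seg_start <- z$start[m_idx[1]]
        seg_end <- z$start[m_idx[length(m_idx)]] + window_bp
        nb <- norm[contig == z$contig[1] & start >= seg_start & start < seg_end]
        mval <- mean(nb[usable == TRUE, t_norm - g_norm]) - baseline
        segs[[length(segs) + 1L]] <- data.table(
          contig = z$contig[1], start = seg_start, end = seg_end,
          mean = mval, state = s$state, n_bins = nrow(nb),
          n_windows = length(m_idx))
      }
    }
  }
  out <- rbindlist(segs)
  setorder(out, contig, start)
  out <- .enforce_disjoint(out)
  setattr(out, "baseline", baseline)
  out[]
}

# mode of the windowed-difference density: the copy-neutral level
.density_mode <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 10) return(0)
  d <- stats::density(v, n = 2048)
  d$x[which.max(d$y)]
}

# sliding windows overlap; clip trailing overlap so segments are disjoint
.enforce_disjoint <- function(segs) {
  if (nrow(segs) < 2) return(segs)
  for (i in 2:nrow(segs)) {
    if (segs$contig[i] == segs$contig[i - 1L] &&
        segs$start[i] < segs$end[i - 1L])
      segs$end[i - 1L] <- segs$start[i]
  }
  segs[end > start]
}

# maximal same-sign runs of flagged windows, tolerating short missing gaps
.flag_runs <- function(code, gap_tolerance) {
  runs <- list()
  cur_sign <- 0L; cur_from <- NA_integer_; cur_to <- NA_integer_; gap <- 0L
  flush <- function() {
    if (cur_sign != 0L)
      runs[[length(runs) + 1L]] <<- list(sign = cur_sign, from = cur_from,
                                         to = cur_to)
  }
  for (i in seq_along(code)) {
    ci <- code[i]
    if (ci == cur_sign && cur_sign != 0L) { cur_to <- i; gap <- 0L }
    else if (ci == 9L && cur_sign != 0L) {
      gap <- gap + 1L
      if (gap > gap_tolerance) { flush(); cur_sign <- 0L; gap <- 0L }
    } else if (ci %in% c(-1L, 1L)) {
      flush(); cur_sign <- ci; cur_from <- i; cur_to <- i; gap <- 0L
    } else { flush(); cur_sign <- 0L; gap <- 0L }
  }
  flush()
  runs
}

# split one same-sign run into state sub-runs; indices relative to the run
.state_split <- function(values, sign, thresholds, min_state_run) {
  if (sign < 0) {
    extreme <- values <= thresholds$homozygous_loss
    states <- c("hemizygous_loss", "homozygous_loss")
  } else {
    extreme <- values >= thresholds$amplified
    states <- c("gain", "amplified")
  }
  r <- rle(extreme)
  # absorb sub-runs shorter than min_state_run into their neighbours
  while (length(r$lengths) > 1 && any(r$lengths < min_state_run)) {
    i <- which.min(r$lengths)
    if (r$lengths[i] >= min_state_run) break
    r$values[i] <- r$values[if (i == 1) 2L else i - 1L]
    r <- rle(inverse.rle(r))
  }
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_along(ends), function(i)
    list(from = starts[i], to = ends[i],
         state = states[1L + as.integer(r$values[i])]))
}

#' Per-chromosome median windowed difference
#'
#' Whole-chromosome gains and losses shift the chromosome's entire window
#' distribution without necessarily exceeding the focal departure rule (a
#' single-copy gain at 60% purity sits near `log2(1.3) = 0.378`); this
#' summary reports them.
#'
#' @param windows output of [windowed_difference()].
#' @return `data.table(contig, median_diff, n_windows)`.
#' @export
chromosome_medians <- function(windows) {
  as.data.table(windows)[!is.na(value),
                         .(median_diff = median(value), n_windows = .N),
                         by = contig]
}

#' Full copy-number calling on a paired coverage track
#'
#' Normalizes both samples to their modal depths, computes the sliding-window
#' log2 difference, flags departures and segments them with zygosity states.
#'
#' @param track paired `coverage_track` (from [simulate_bin_depths()] or
#'   [pair_coverage_tracks()]).
#' @param window_bp sliding-window size (default 2000).
#' @param departure flag threshold (default 0.75).
#' @param ... passed to [flag_and_segment()].
#' @return List with `segments`, `windows`, `normtab`,
#'   `chromosome_medians`.
#' @export
cnv_call <- function(track, window_bp = 2000L, departure = 0.75, ...) {
  normtab <- normalized_log2(track)
  win <- windowed_difference(normtab, window_bp = window_bp)
  segments <- flag_and_segment(win, normtab, departure = departure, ...)
  list(segments = segments, windows = win, normtab = normtab,
       chromosome_medians = chromosome_medians(win))
}

#' Exon-restricted moderate-deletion scan
#'
#' The coding-exon variant of the copy-number analysis: base (sequence)
#' coverage rather than fragment (clonal) coverage, evaluated per exon. Each
#' exon's value is the mean `t_norm - g_norm` over its usable bins under the
#' same normalization; the same departure rule flags it. Exons whose germline
#' coverage is zero are reported as `no_data`.
#'
#' @param track paired base-kind `coverage_track`.
#' @param exons `data.frame(contig, start, end)` (0-based half-open; merged
#'   if overlapping).
#' @param departure flag threshold (default 0.75).
#' @return `data.table(contig, start, end, value, n_bins, status)` with
#'   `status` in `flagged_loss` / `flagged_gain` / `neutral` / `no_data`.
#' @export
exon_moderate_deletions <- function(track, exons, departure = 0.75) {
  exons <- as.data.table(exons)[, .(contig, start = as.integer(start),
                                    end = as.integer(end))]
  if (any(exons$end <= exons$start)) stop("invalid exon interval")
  setorder(exons, contig, start)
  # merge overlapping exons
  merged <- exons[, {
    ir <- IRanges::reduce(IRanges::IRanges(start + 1L, end), min.gapwidth = 0L)
    .(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  }, by = contig]
  normtab <- normalized_log2(track)
  bin_size <- attr(track, "bin_size") %||% 100L
  out <- merged[, .(contig, start, end)]
  out[, `:=`(value = NA_real_, n_bins = 0L, status = "no_data")]
  for (i in seq_len(nrow(out))) {
    nb <- normtab[contig == out$contig[i] &
                    start + bin_size > out$start[i] & start < out$end[i]]
    out$n_bins[i] <- nrow(nb)
    nbu <- nb[usable == TRUE]
    val <- if (nrow(nbu)) mean(nbu$t_norm - nbu$g_norm) else NA_real_
    out$value[i] <- val
    out$status[i] <- if (sum(nb$germline) == 0 || is.na(val)) "no_data"
    else if (val < -departure) "flagged_loss"
    else if (val > departure) "flagged_gain"
    else "neutral"
  }
  out[]
}
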
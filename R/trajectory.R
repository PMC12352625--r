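# Trajectory statistics: water residence near Fe, distance series,
# hydrogen-bond occupancy, and mode (bimodality) detection.
#
# No periodic-boundary imaging is applied: frames are assumed whole and
# imaged around the protein, as for a solvated protein-centred site.

#' Construct a Trajectory
#'
#' @param topology a single-model [Structure] naming the atoms.
#' @param frames list of N x 3 coordinate matrices (Angstrom), all with
#'   the topology's atom count; defaults to the topology's own models.
#' @param dt_label free-text description of the frame spacing.
#' @return an object of class `Trajectory`.
#' @export
Trajectory <- function(topology, frames = NULL, dt_label = "") {
  if (is.null(frames))
    frames <- lapply(topology$models, coords)
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (ncol(f) != 3L) stop("frames must be N x 3 matrices")
    f
  })
  if (!length(frames)) stop("a trajectory needs at least one frame")
  na <- nrow(topology$models[[1]])
  if (any(vapply(frames, nrow, 1L) != na))
    stop("all frames must have the topology's atom count (", na, ")")
  topo <- Structure(topology$models[1], topology$source_format, topology$id)
  structure(list(topology = topo, frames = frames, dt_label = dt_label),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms %s\n", length(x$frames),
              nrow(x$topology$models[[1]]),
              if (nzchar(x$dt_label)) paste0("(", x$dt_label, ")") else ""))
  invisible(x)
}

#' Read a trajectory from a multi-model PDB or XYZ stack
#'
#' @param path file path; each MODEL (PDB) or frame (XYZ) becomes one
#'   trajectory frame; the first frame provides the topology.
#' @param format_hint optional format override, see [read_structure()].
#' @return a [Trajectory].
#' @export
read_trajectory <- function(path, format_hint = NULL) {
  s <- read_structure(path, format_hint)
  Trajectory(s, frames = lapply(s$models, coords))
}

frame_dist <- function(frame, i, j) sqrt(sum((frame[i, ] - frame[j, ])^2))

#' Per-frame distance statistics for an atom pair
#'
#' @param t a [Trajectory].
#' @param a,b atom handles (topology row indices).
#' @param bin_width histogram bin width, Angstrom (default 0.05).
#' @return list with `distances` (per frame), `mean`, `sd` (sample,
#'   n-1 denominator), and `histogram` (`breaks`, `counts`, `mids`).
#' @export
distance_series <- function(t, a, b, bin_width = 0.05) {
  d <- vapply(t$frames, frame_dist, numeric(1), i = a, j = b)
  list(distances = d, mean = mean(d),
       sd = if (length(d) > 1) stats::sd(d) else 0,
       histogram = make_histogram(d, bin_width))
}

make_histogram <- function(d, bin_width) {
  if (!length(d)) return(list(breaks = numeric(0), counts = integer(0),
                              mids = numeric(0)))
  lo <- floor(min(d) / bin_width) * bin_width
  hi <- ceiling(max(d) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  list(breaks = h$breaks, counts = h$counts, mids = h$mids)
}

water_oxygen_handles <- function(topology,
                                 water_resnames = c("HOH", "WAT", "TIP3")) {
  m <- topology$models[[1]]
  which(m$resname %in% water_resnames & m$element == "O")
}

#' Water residence near the haem iron
#'
#' Per frame, takes the minimum Fe to water-oxygen distance; a frame
#' "contributes" when that minimum is within `cutoff`. Occupancy is the
#' fraction of contributing frames. By convention (matching how residence
#' statistics are usually quoted for a coordination site) the mean and sd
#' are computed over contributing frames only; `all_frames = TRUE` uses
#' every frame instead.
#'
#' @param t a [Trajectory].
#' @param fe atom handle of the iron.
#' @param cutoff residence cutoff, Angstrom (default 3.5).
#' @param water_resnames residue names treated as water.
#' @param bin_width histogram bin width (default 0.05 A).
#' @param all_frames if `TRUE`, mean/sd/histogram over all frames with
#'   any water, not only contributing frames.
#' @return a `ResidenceProfile` list: `cutoff`, `per_frame_min_dist`,
#'   `occupancy`, `mean`, `sd`, `histogram`, `modes`.
#' @export
water_residence <- function(t, fe, cutoff = 3.5,
                            water_resnames = c("HOH", "WAT", "TIP3"),
                            bin_width = 0.05, all_frames = FALSE) {
  if (!length(t$frames)) stop("trajectory has no frames")
  wo <- water_oxygen_handles(t$topology, water_resnames)
  if (!length(wo)) {
    return(structure(list(cutoff = cutoff,
                          per_frame_min_dist = rep(NA_real_,
                                                   length(t$frames)),
                          occupancy = 0, mean = NA_real_, sd = NA_real_,
                          histogram = make_histogram(numeric(0), bin_width),
                          modes = numeric(0)),
                     class = "ResidenceProfile"))
  }
  dmin <- vapply(t$frames, function(f) {
    sqrt(min(rowSums(sweep(f[wo, , drop = FALSE], 2, f[fe, ])^2)))
  }, numeric(1))
  contrib <- dmin <= cutoff
  use <- if (all_frames) dmin else dmin[contrib]
  h <- make_histogram(use, bin_width)
  structure(list(cutoff = cutoff, per_frame_min_dist = dmin,
                 occupancy = mean(contrib),
                 mean = if (length(use)) mean(use) else NA_real_,
                 sd = if (length(use) > 1) stats::sd(use) else
                   if (length(use) == 1) 0 else NA_real_,
                 histogram = h,
                 modes = if (length(use)) detect_modes(h) else numeric(0)),
            class = "ResidenceProfile")
}

#' @export
print.ResidenceProfile <- function(x, ...) {
  cat(sprintf(
    "ResidenceProfile (cutoff %.2f A): occupancy %.3f, %.2f +/- %.2f A, %d mode(s)\n",
    x$cutoff, x$occupancy, x$mean, x$sd, length(x$modes)))
  invisible(x)
}

#' Hydrogen-bond criteria
#'
#' Default geometric criteria: donor-acceptor heavy-atom distance at most
#' 3.5 A and, when hydrogens are present, a D-H...A angle of at least 120
#' degrees.
#'
#' @param da_max donor-acceptor cutoff, Angstrom.
#' @param dha_min_deg minimum D-H...A angle, degrees.
#' @param mode `"heavy_only"` (distance criterion only) or
#'   `"with_hydrogens"` (distance and angle).
#' @return an `HBondCriteria` list.
#' @export
hbond_criteria <- function(da_max = 3.5, dha_min_deg = 120,
                           mode = c("heavy_only", "with_hydrogens")) {
  mode <- match.arg(mode)
  stopifnot(da_max > 0, dha_min_deg >= 0, dha_min_deg <= 180)
  structure(list(da_max = da_max, dha_min_deg = dha_min_deg, mode = mode),
            class = "HBondCriteria")
}

angle_deg <- function(a, b, c) {
  # angle at b, degrees
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' Fraction of frames in which the donor-acceptor pair satisfies the
#' geometric criteria. In `with_hydrogens` mode the angle criterion is met
#' if any supplied hydrogen gives a D-H...A angle at or above the minimum.
#'
#' @param t a [Trajectory].
#' @param donor,acceptor heavy-atom handles.
#' @param hydrogens handles of the donor's hydrogens (may be empty in
#'   `heavy_only` mode).
#' @param criteria an [hbond_criteria()] object.
#' @return occupancy fraction in `[0, 1]`.
#' @export
hbond_occupancy <- function(t, donor, acceptor, hydrogens = integer(0),
                            criteria = hbond_criteria()) {
  if (criteria$mode == "with_hydrogens" && !length(hydrogens))
    stop("with_hydrogens mode requires hydrogen handles")
  ok <- vapply(t$frames, function(f) {
    if (frame_dist(f, donor, acceptor) > criteria$da_max) return(FALSE)
    if (criteria$mode == "heavy_only") return(TRUE)
    any(vapply(hydrogens, function(h)
      angle_deg(f[donor, ], f[h, ], f[acceptor, ]) >= criteria$dha_min_deg,
      logical(1)))
  }, logical(1))
  mean(ok)
}

box_smooth <- function(counts, k) {
  if (k <= 1L || length(counts) < 2L) return(as.numeric(counts))
  half <- (k - 1L) %/% 2L
  n <- length(counts)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(counts[lo:hi])
  }, numeric(1))
}

#' Detect modes of a distance histogram
#'
#' Box-smooths the counts and reports local maxima that are separated by
#' at least `min_separation` and reach at least `prominence` of the
#' global maximum. A flat histogram yields a single mode at the
#' count-weighted centre.
#'
#' @param histogram list with `mids` and `counts`
#'   (as from [distance_series()]).
#' @param smoothing box width in bins (default 3).
#' @param min_separation minimum distance between reported modes,
#'   Angstrom (default 0.15).
#' @param prominence minimum peak height as a fraction of the highest
#'   smoothed count (default 0.10).
#' @return numeric vector of mode centres (Angstrom), ascending.
#' @export
detect_modes <- function(histogram, smoothing = 3L, min_separation = 0.15,
                         prominence = 0.10) {
  mids <- histogram$mids
  counts <- as.numeric(histogram$counts)
  if (!length(mids)) stop("empty histogram")
  if (length(mids) == 1L) return(mids)
  sm <- box_smooth(counts, smoothing)
  if (max(sm) == min(sm))
    return(sum(mids * counts) / sum(counts))
  n <- length(sm)
  is_peak <- vapply(seq_len(n), function(i) {
    left <- if (i > 1L) sm[i - 1L] else -Inf
    right <- if (i < n) sm[i + 1L] else -Inf
    sm[i] >= left && sm[i] >= right && (sm[i] > left || sm[i] > right)
  }, logical(1))
  # plateaus: keep only the first bin of any run of equal peak values
  pk <- which(is_peak)
  if (length(pk) > 1L) {
    drop <- c(FALSE, diff(pk) == 1L & sm[pk[-length(pk)]] == sm[pk[-1L]])
    pk <- pk[!drop]
  }
  pk <- pk[sm[pk] >= prominence * max(sm)]
  if (!length(pk)) return(mids[which.max(sm)])
  # enforce separation, keeping the taller peak
  pk <- pk[order(-sm[pk], mids[pk])]
  kept <- integer(0)
  for (i in pk) {
    if (all(abs(mids[i] - mids[kept]) >= min_separation)) kept <- c(kept, i)
  }
  sort(mids[kept])
}
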
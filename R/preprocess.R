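# Single-subject temporal preprocessing: initial-volume discard, motion
# quality control, per-voxel linear detrending, and ideal (frequency-
# rectangular) band-pass filtering.  Spatial registration steps are out of
# scope: images are assumed to sit on a common grid already.

#' Motion parameter table
#'
#' Six rigid-body parameters per volume: three translations (mm) and three
#' rotations.  The rotation unit must be declared explicitly — the SPM
#' `rp_*.txt` dialect stores radians while screening thresholds are usually
#' quoted in degrees, and guessing silently is the classic QC bug.
#'
#' @param translations T x 3 numeric matrix, mm.
#' @param rotations T x 3 numeric matrix.
#' @param rotation_unit `"radians"` or `"degrees"`.
#' @return An object of class `motion_params` (rotations stored in degrees).
#' @export
motion_params <- function(translations, rotations, rotation_unit) {
  if (missing(rotation_unit) || is.null(rotation_unit))
    stopf("`rotation_unit` must be declared ('radians' or 'degrees'); refusing to guess")
  rotation_unit <- match.arg(rotation_unit, c("radians", "degrees"))
  translations <- as.matrix(translations)
  rotations <- as.matrix(rotations)
  if (ncol(translations) != 3L || ncol(rotations) != 3L)
    stopf("translations and rotations must each have 3 columns")
  if (nrow(translations) != nrow(rotations) || nrow(translations) < 1L)
    stopf("translations and rotations must have the same, positive row count")
  if (rotation_unit == "radians") rotations <- rotations * 180 / pi
  structure(list(translations = translations, rotations = rotations),
            class = "motion_params")
}

#' Read an SPM-style motion parameter file
#'
#' Whitespace-delimited text, one row per volume, six columns: x/y/z
#' translation (mm) then three rotations in the declared unit.
#'
#' @param path text file.
#' @param rotation_unit `"radians"` (the SPM rp_*.txt convention) or
#'   `"degrees"`; no default, the unit must be stated.
#' @return A [motion_params()] object.
#' @export
read_motion_params <- function(path, rotation_unit) {
  if (missing(rotation_unit))
    stopf("`rotation_unit` must be declared ('radians' or 'degrees'); refusing to guess")
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6L)
    stopf("%s: expected 6 columns of motion parameters, found %d", path, ncol(m))
  motion_params(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE], rotation_unit)
}

#' Discard initial volumes of a BOLD run
#'
#' Drops the first `n_discard` volumes (scanner signal equilibration /
#' subject adaptation period); the remaining volumes are preserved
#' bit-exactly, with affine and TR unchanged.
#'
#' @param bold a [bold4d()].
#' @param n_discard number of leading volumes to drop (default 10).
#' @return A [bold4d()] with T - n_discard volumes.
#' @export
discard_initial_volumes <- function(bold, n_discard = 10L) {
  stopifnot(inherits(bold, "bold4d"))
  nt <- dim(bold$data)[4]
  n_discard <- as.integer(n_discard)
  if (n_discard < 0L) stopf("`n_discard` must be non-negative")
  if (n_discard >= nt)
    stopf("discarding %d of %d volumes would leave no data", n_discard, nt)
  bold4d(bold$data[, , , (n_discard + 1L):nt, drop = FALSE],
         bold$affine, bold$tr_s)
}

#' Motion quality-control gate
#'
#' A dataset fails if any translation exceeds `max_trans_mm` in absolute
#' value on any axis, or any rotation exceeds `max_rot_deg` on any axis.
#'
#' @param motion a [motion_params()].
#' @param max_trans_mm translation threshold, mm (default 1.5).
#' @param max_rot_deg rotation threshold, degrees (default 1).
#' @return list with `pass` (logical), `max_translation_mm` and
#'   `max_rotation_deg` (named length-3 vectors of per-axis absolute maxima).
#' @export
qc_motion <- function(motion, max_trans_mm = 1.5, max_rot_deg = 1) {
  stopifnot(inherits(motion, "motion_params"))
  mt <- apply(abs(motion$translations), 2, max)
  mr <- apply(abs(motion$rotations), 2, max)
  names(mt) <- names(mr) <- c("x", "y", "z")
  list(pass = all(mt <= max_trans_mm) && all(mr <= max_rot_deg),
       max_translation_mm = mt, max_rotation_deg = mr)
}

#' Per-voxel linear detrending
#'
#' Removes each voxel's least-squares line over time and restores its
#' original temporal mean, so only the linear drift (and not the offset) is
#' taken out.
#'
#' @param bold a [bold4d()] with at least 3 volumes.
#' @return A detrended [bold4d()].
#' @export
detrend_linear <- function(bold) {
  stopifnot(inherits(bold, "bold4d"))
  d <- dim(bold$data)
  nt <- d[4]
  if (nt < 3L) stopf("detrending needs at least 3 volumes, got %d", nt)
  tc <- seq_len(nt) - (nt + 1) / 2            # centered time
  M <- matrix(bold$data, ncol = nt)           # V x T
  slope <- (M %*% tc) / sum(tc^2)
  out <- M - slope %*% t(tc)                  # y - b*(t - tbar): mean kept
  bold4d(array(out, d), bold$affine, bold$tr_s)
}

#' Band-pass filter specification
#'
#' @param low_hz lower edge (Hz), >= 0.
#' @param high_hz upper edge (Hz), > low_hz.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 0.01, high_hz = 0.08) {
  stopifnot(is.numeric(low_hz), is.numeric(high_hz))
  if (!(low_hz >= 0 && low_hz < high_hz))
    stopf("need 0 <= low_hz < high_hz, got [%g, %g]", low_hz, high_hz)
  structure(list(low_hz = low_hz, high_hz = high_hz), class = "filter_spec")
}

#' Ideal (frequency-rectangular) band-pass filter
#'
#' Per voxel, the discrete Fourier components whose frequency f satisfies
#' low_hz <= f <= high_hz (inclusive at both edges) are kept and all others
#' zeroed; the zero-frequency component is retained so the output temporal
#' mean equals the input mean.  This is the sharp-edged filter convention
#' of the REST resting-state toolchain.
#'
#' @param bold a [bold4d()].
#' @param spec a [filter_spec()]; `high_hz` must not exceed the Nyquist
#'   frequency 1/(2 TR).
#' @return A filtered [bold4d()].
#' @export
bandpass_ideal <- function(bold, spec = filter_spec()) {
  stopifnot(inherits(bold, "bold4d"), inherits(spec, "filter_spec"))
  nyq <- 1 / (2 * bold$tr_s)
  if (spec$high_hz > nyq + 1e-12)
    stopf("high_hz = %g Hz exceeds the Nyquist frequency %g Hz at TR = %g s",
          spec$high_hz, nyq, bold$tr_s)
  d <- dim(bold$data)
  nt <- d[4]
  freq <- (seq_len(nt) - 1) / (nt * bold$tr_s)
  freq <- pmin(freq, 1 / bold$tr_s - freq)    # fold to [0, Nyquist]
  keep <- (freq >= spec$low_hz & freq <= spec$high_hz)
  keep[1] <- TRUE                             # DC: preserve the mean
  M <- matrix(bold$data, ncol = nt)           # V x T, series in rows
  sp <- t(stats::mvfft(t(M)))                 # V x T spectra
  sp[, !keep] <- 0
  out <- Re(t(stats::mvfft(t(sp), inverse = TRUE))) / nt
  bold4d(array(out, d), bold$affine, bold$tr_s)
}
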
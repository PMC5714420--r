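# Evaluation surface: depth-dose and profile extraction, mean relative
# difference, 2-D gamma index, and the Monte Carlo efficiency metric.

.dose_curve <- function(coordinate, value) {
  structure(data.frame(coordinate = coordinate, value = value),
            class = c("dose_curve", "data.frame"))
}

.axis_centers <- function(dose, axis) {
  dose$grid$origin[axis] +
    (seq_len(dose$grid$shape[axis]) - 0.5) * dose$grid$voxel_size[axis]
}

#' Extract the central-axis percent depth dose
#'
#' Depth-dose along the beam axis, averaged over a small lateral
#' neighbourhood to reduce Monte Carlo noise, normalized to 100 at its
#' maximum. Depth is measured from the beam-entry (top) surface.
#'
#' @param dose a `dose_grid`.
#' @param axis_position lateral position `c(x, y)` of the axis \[cm\].
#' @param lateral_window half-width of the averaging window \[cm\]; the
#'   default corresponds to a 3 x 3 voxel neighbourhood at the default
#'   voxel size.
#' @param what dose array to use.
#' @param normalize normalize the curve to max = 100 (idempotent).
#' @return a `dose_curve` data.frame with `coordinate` (depth, cm,
#'   increasing) and `value`.
#' @export
extract_pdd <- function(dose, axis_position = c(0, 0),
                        lateral_window = 1.5 * dose$grid$voxel_size[1],
                        what = c("dose_water", "dose_medium"),
                        normalize = TRUE) {
  what <- match.arg(what)
  cx <- .axis_centers(dose, 1); cy <- .axis_centers(dose, 2)
  ix <- which(abs(cx - axis_position[1]) <= lateral_window)
  iy <- which(abs(cy - axis_position[2]) <= lateral_window)
  if (!length(ix) || !length(iy)) stop("axis outside grid")
  v <- apply(dose[[what]][ix, iy, , drop = FALSE], 3, mean)
  depth <- rev(dose$grid$shape[3]:1 - 0.5) * dose$grid$voxel_size[3]
  v <- rev(v) # depth increases downward from the entry surface
  if (normalize && max(v) > 0) v <- 100 * v / max(v)
  .dose_curve(depth, v)
}

#' Depth of the dose maximum
#'
#' Either the raw argmax of the curve, or (default) the maximum of a
#' smooth buildup model `A (exp(-a d) - exp(-b d))` fitted to the curve by
#' nonlinear least squares -- the standard way to locate a flat Monte Carlo
#' depth-dose maximum in the presence of noise; falls back to the argmax
#' if the fit fails.
#'
#' @param curve a `dose_curve` from [extract_pdd()].
#' @param method `"fit"` or `"argmax"`.
#' @param fit_range depths \[cm\] used for the fit.
#' @return depth of maximum \[cm\].
#' @export
depth_of_maximum <- function(curve, method = c("fit", "argmax"),
                             fit_range = c(0, 10)) {
  method <- match.arg(method)
  d_arg <- curve$coordinate[which.max(curve$value)]
  if (method == "argmax") return(d_arg)
  sel <- curve$coordinate >= fit_range[1] & curve$coordinate <= fit_range[2]
  df <- data.frame(d = curve$coordinate[sel], v = curve$value[sel])
  fit <- tryCatch(
    stats::nls(v ~ A * (exp(-a * d) - exp(-b * d)), data = df,
               start = list(A = max(df$v) * 1.2, a = 0.04, b = 6),
               lower = c(A = 0, a = 1e-4, b = 0.1), algorithm = "port",
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) return(d_arg)
  cf <- coef(fit)
  if (cf["b"] <= cf["a"]) return(d_arg)
  unname(log(cf["b"] / cf["a"]) / (cf["b"] - cf["a"]))
}

#' Extract a lateral dose profile
#'
#' 1-D profile across the beam at a given depth, averaged over a small
#' window in the two orthogonal directions.
#'
#' @param dose a `dose_grid`.
#' @param depth depth below the entry surface \[cm\].
#' @param along `"y"` (long field axis) or `"x"`.
#' @param at position on the other lateral axis \[cm\].
#' @param window half-width of the averaging window \[cm\].
#' @param what dose array to use.
#' @param normalize `"max"` (100 at maximum), `"half"` (the display
#'   convention scaling to 50% of maximum), or `"none"`.
#' @return a `dose_curve`.
#' @export
extract_profile <- function(dose, depth, along = c("y", "x"), at = 0,
                            window = 1.5 * dose$grid$voxel_size[3],
                            what = c("dose_water", "dose_medium"),
                            normalize = c("max", "half", "none")) {
  along <- match.arg(along)
  what <- match.arg(what)
  normalize <- match.arg(normalize)
  ztop <- dose$grid$origin[3] + dose$grid$shape[3] * dose$grid$voxel_size[3]
  cz <- .axis_centers(dose, 3)
  iz <- which(abs((ztop - cz) - depth) <= window)
  if (!length(iz)) stop("depth outside grid")
  a_main <- if (along == "y") 2 else 1
  a_other <- if (along == "y") 1 else 2
  co <- .axis_centers(dose, a_other)
  io <- which(abs(co - at) <= window)
  if (!length(io)) stop("profile line outside grid")
  arr <- dose[[what]]
  sub <- if (along == "y") arr[io, , iz, drop = FALSE] else
    arr[, io, iz, drop = FALSE]
  v <- apply(sub, a_main, mean)
  if (normalize != "none" && max(v) > 0)
    v <- v / max(v) * if (normalize == "max") 100 else 50
  .dose_curve(.axis_centers(dose, a_main), v)
}

#' @export
plot.dose_curve <- function(x, ...) {
  graphics::plot(x$coordinate, x$value, type = "l",
                 xlab = "position [cm]", ylab = "dose [%]", ...)
  invisible(x)
}

#' Mean relative difference between two dose curves
#'
#' The second curve is resampled onto the first curve's coordinates by
#' linear interpolation; the result is the mean of `|a - b| / a` in
#' percent over points where the reference curve is above a low-value
#' threshold. Values are compared as given (no renormalization), so the
#' metric is invariant to a common rescaling of both curves but sensitive
#' to a relative one.
#'
#' @param a reference `dose_curve`.
#' @param b evaluated `dose_curve`.
#' @param threshold exclude points where `a` is below this fraction (in
#'   percent) of its maximum.
#' @return mean relative difference in percent.
#' @export
mean_relative_difference <- function(a, b, threshold = 10) {
  lo <- max(min(a$coordinate), min(b$coordinate))
  hi <- min(max(a$coordinate), max(b$coordinate))
  if (lo >= hi) stop("curves have disjoint supports")
  sel <- a$coordinate >= lo & a$coordinate <= hi &
    a$value >= threshold / 100 * max(a$value) & a$value > 0
  bv <- approx(b$coordinate, b$value, xout = a$coordinate[sel])$y
  mean(abs(a$value[sel] - bv) / a$value[sel]) * 100
}

# bilinear resample of a matrix onto finer spacing
.refine_plane <- function(m, spacing, target) {
  f <- ceiling(spacing / target)
  if (all(f <= 1)) return(list(m = m, spacing = spacing))
  x0 <- (seq_len(nrow(m)) - 1) * spacing[1]
  y0 <- (seq_len(ncol(m)) - 1) * spacing[2]
  x1 <- seq(0, max(x0), by = spacing[1] / f[1])
  y1 <- seq(0, max(y0), by = spacing[2] / f[2])
  tmp <- apply(m, 2, function(col) approx(x0, col, xout = x1)$y)
  out <- t(apply(tmp, 1, function(row) approx(y0, row, xout = y1)$y))
  list(m = out, spacing = c(spacing[1] / f[1], spacing[2] / f[2]))
}

#' 2-D gamma index between two dose planes
#'
#' Standard gamma analysis: for every reference point the minimum over
#' evaluated points of `sqrt((dr/dta)^2 + (dD / (dd/100 * Dmax))^2)`; a
#' point passes when gamma <= 1. The dose-difference criterion is global
#' (percent of the reference plane maximum) by default. If the evaluated
#' plane's spacing is coarser than `dta / 3` it is refined by bilinear
#' interpolation first (with a warning when coarser than `dta`). The
#' search is restricted to a radius of `search_cap * dta`, which bounds
#' reported gamma values but cannot change pass/fail decisions.
#'
#' @param reference,evaluated dose planes (numeric matrices).
#' @param dta distance-to-agreement criterion \[mm\].
#' @param dd dose-difference criterion \[% of maximum dose\].
#' @param spacing pixel spacing of `reference` \[mm\], length 2 (recycled).
#' @param spacing_eval pixel spacing of `evaluated` \[mm\].
#' @param threshold low-dose cutoff: reference points below this percent
#'   of the maximum are excluded from the pass rate.
#' @param normalization `"global"` (percent of plane maximum) or
#'   `"local"` (percent of the local reference dose).
#' @param search_cap search radius in units of `dta`.
#' @return object of class `gamma_result`: `gamma_map`, logical `mask` of
#'   analysed points, `pass_rate` (percent), `dta`, `dd`.
#' @export
gamma_index <- function(reference, evaluated, dta = 3, dd = 3,
                        spacing = 1, spacing_eval = spacing,
                        threshold = 10,
                        normalization = c("global", "local"),
                        search_cap = 3) {
  normalization <- match.arg(normalization)
  spacing <- rep_len(spacing, 2)
  spacing_eval <- rep_len(spacing_eval, 2)
  if (any(spacing_eval > dta))
    warning("evaluated-plane spacing coarser than dta; interpolating")
  ev <- .refine_plane(evaluated, spacing_eval, dta / 3)
  em <- ev$m; es <- ev$spacing
  dmax <- max(reference)
  nr <- nrow(reference); nc <- ncol(reference)
  # offsets within the search radius, nearest first
  ni <- floor(search_cap * dta / es[1]); nj <- floor(search_cap * dta / es[2])
  off <- expand.grid(di = -ni:ni, dj = -nj:nj)
  off$d2 <- (off$di * es[1])^2 + (off$dj * es[2])^2
  off <- off[off$d2 <= (search_cap * dta)^2, ]
  off <- off[order(off$d2), ]
  gmap <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    x <- (i - 1) * spacing[1]
    ei0 <- round(x / es[1]) + 1
    for (j in seq_len(nc)) {
      y <- (j - 1) * spacing[2]
      ej0 <- round(y / es[2]) + 1
      denom <- dd / 100 * if (normalization == "global") dmax else
        reference[i, j]
      best <- Inf
      for (o in seq_len(nrow(off))) {
        dist2 <- off$d2[o] / dta^2
        if (dist2 >= best) break
        ei <- ei0 + off$di[o]; ej <- ej0 + off$dj[o]
        if (ei < 1 || ej < 1 || ei > nrow(em) || ej > ncol(em)) next
        g2 <- dist2 + ((em[ei, ej] - reference[i, j]) / denom)^2
        if (g2 < best) best <- g2
      }
      gmap[i, j] <- sqrt(best)
    }
  }
  mask <- reference >= threshold / 100 * dmax
  structure(list(gamma_map = gmap, mask = mask,
                 pass_rate = 100 * mean(gmap[mask] <= 1),
                 dta = dta, dd = dd), class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %.1f mm / %.1f%%: pass rate %.1f%% (%d points)\n",
              x$dta, x$dd, x$pass_rate, sum(x$mask)))
  invisible(x)
}

#' Mean dose in a scoring box
#'
#' @param dose a `dose_grid`.
#' @param center box centre `c(x, y, z)` in world coordinates \[cm\].
#' @param size box edge lengths \[cm\] (recycled to length 3).
#' @param what dose array to use.
#' @return mean dose over the voxels whose centres fall in the box.
#' @export
box_dose <- function(dose, center, size = 2,
                     what = c("dose_water", "dose_medium")) {
  what <- match.arg(what)
  size <- rep_len(size, 3)
  idx <- lapply(1:3, function(a) {
    ca <- .axis_centers(dose, a)
    which(abs(ca - center[a]) <= size[a] / 2)
  })
  if (!all(lengths(idx) > 0)) stop("scoring box outside grid")
  mean(dose[[what]][idx[[1]], idx[[2]], idx[[3]]])
}

#' Monte Carlo efficiency of a simulation setup
#'
#' Runs `run_fn` repeatedly, records the mean dose in a scoring box and
#' the total wall time, and returns the figure of merit
#' `efficiency = 1 / (variance x time)`.
#'
#' @param run_fn function of a run index returning a `dose_grid` (it
#'   should vary the seed with the index).
#' @param n_runs number of repeat simulations (>= 2).
#' @param box_center,box_size scoring box, as in [box_dose()].
#' @return list with `efficiency`, `variance`, `time` \[s\], `doses` and
#'   a `degenerate` flag (zero variance).
#' @export
estimate_efficiency <- function(run_fn, n_runs = 10, box_center,
                                box_size = 2) {
  stopifnot(n_runs >= 2)
  t0 <- proc.time()[["elapsed"]]
  doses <- vapply(seq_len(n_runs),
                  function(i) box_dose(run_fn(i), box_center, box_size),
                  numeric(1))
  elapsed <- proc.time()[["elapsed"]] - t0
  v <- var(doses)
  degenerate <- !is.finite(v) || v <= 0
  if (degenerate) warning("degenerate (zero-variance) scoring box")
  list(efficiency = if (degenerate) Inf else 1 / (v * elapsed),
       variance = v, time = elapsed, doses = doses, degenerate = degenerate)
}
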
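## Friction observables: hooking fraction, interlayer distance, regime
## classification, critical velocity, U-h correlation.

#' Hooking (interpenetration) fraction of a configuration
#'
#' Fraction (in percent) of molecules whose cation (CA) bead has crossed
#' the opposing layer's mean cation plane by at least `dz`, counted over
#' both layers.  With `reference = "AN"` the anion plane is used instead.
#'
#' @param sys a `zw_system` (for the layer tags and species).
#' @param positions optional N x 3 matrix overriding `sys$positions`.
#' @param dz crossing margin, nm.
#' @param reference head bead defining the reference plane, `"CA"` or `"AN"`.
#' @return hooking fraction h in percent, in `[0, 100]`.
#' @export
hooking_fraction <- function(sys, positions = NULL, dz = 0,
                             reference = c("CA", "AN")) {
  reference <- match.arg(reference)
  pos <- if (is.null(positions)) sys$positions else positions
  if (is.null(sys$layer) || is.null(sys$species))
    stop("system is missing layer tags or species labels")
  sel <- sys$species == reference
  sub <- sel & sys$layer == 0L
  sup <- sel & sys$layer == 1L
  if (!any(sub) || !any(sup)) stop("both layers must carry ", reference,
                                   " beads")
  z_sub <- pos[sub, 3]; z_sup <- pos[sup, 3]
  cnt <- sum(z_sub > mean(z_sup) + dz) + sum(z_sup < mean(z_sub) - dz)
  100 * cnt / (sum(sub) + sum(sup))
}

#' Interlayer distance
#'
#' Mean z of the SUP rigid beads minus mean z of the SUB rigid beads.
#'
#' @inheritParams hooking_fraction
#' @return distance in nm.
#' @export
interlayer_distance <- function(sys, positions = NULL) {
  pos <- if (is.null(positions)) sys$positions else positions
  sub <- sys$group == 0L
  sup <- sys$group == 1L
  if (!any(sub) || !any(sup)) stop("both rigid layers must be present")
  mean(pos[sup, 3]) - mean(pos[sub, 3])
}

#' Pearson correlation between potential energy and hooking fraction
#'
#' Single-pass (streaming) implementation of the Pearson correlation
#' coefficient `rho = cov(U, h) / (sd(U) sd(h))`.  Returns `NA` (with a
#' message attribute) when either series has zero variance -- in smooth
#' sliding h is identically zero and the correlation is undefined.
#'
#' @param u numeric series (e.g. total potential energy per frame).
#' @param h numeric series of equal length (e.g. hooking fraction).
#' @return correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
pearson_rho <- function(u, h) {
  if (length(u) != length(h)) stop("series lengths differ: ",
                                   length(u), " vs ", length(h))
  n <- length(u)
  if (n < 2) return(NA_real_)
  ## streaming (Welford-style) co-moments
  mu <- 0; mh <- 0; cuh <- 0; vu <- 0; vh <- 0
  for (i in seq_len(n)) {
    du <- u[i] - mu; dh <- h[i] - mh
    mu <- mu + du / i
    mh <- mh + dh / i
    cuh <- cuh + du * (h[i] - mh)
    vu <- vu + du * (u[i] - mu)
    vh <- vh + dh * (h[i] - mh)
  }
  if (vu <= 0 || vh <= 0) {
    out <- NA_real_
    attr(out, "reason") <- "zero variance (h = const: smooth sliding?)"
    return(out)
  }
  cuh / sqrt(vu * vh)
}

#' Detect slip events in a shear-stress trace
#'
#' A slip is a drop of the shear stress by at least `f_drop` times the
#' preceding local maximum, completed within `dx_slip` of stage travel, with
#' an absolute drop of at least `min_drop` (to ignore thermal ripple on
#' low-stress smooth traces).
#'
#' @param trace a `zw_trace` (needs `x_stage` and `stress` columns).
#' @param f_drop fractional drop threshold.
#' @param dx_slip maximum stage travel over which the drop must occur, nm.
#' @param min_drop minimum absolute stress drop, MPa.
#' @return data.frame with one row per event: `x_peak`, `x_end`,
#'   `stress_peak`, `stress_end`.
#' @export
find_slip_events <- function(trace, f_drop = 0.5, dx_slip = 1.0,
                             min_drop = 0.5) {
  x <- trace$x_stage; s <- trace$stress
  ev <- NULL
  n <- length(s)
  peak <- s[1]; xpeak <- x[1]
  i <- 2
  while (i <= n) {
    if (s[i] >= peak) {
      peak <- s[i]; xpeak <- x[i]
    } else if (peak - s[i] >= max(f_drop * peak, min_drop) &&
               x[i] - xpeak <= dx_slip && peak > 0) {
      ## extend the event to the bottom of the drop: follow the running
      ## minimum until the stress recovers appreciably (10% of the drop so
      ## far, at least the minimum drop) or the slip window is exhausted
      smin <- s[i]; imin <- i
      j <- i + 1
      while (j <= n && x[j] - xpeak <= dx_slip) {
        if (s[j] < smin) { smin <- s[j]; imin <- j }
        if (s[j] - smin > max(0.1 * (peak - smin), min_drop)) break
        j <- j + 1
      }
      ev <- rbind(ev, data.frame(x_peak = xpeak, x_end = x[imin],
                                 stress_peak = peak, stress_end = smin))
      peak <- smin; xpeak <- x[imin]
      i <- imin
    } else if (x[i] - xpeak > dx_slip) {
      ## too slow to count as a slip; restart tracking from running level
      peak <- s[i]; xpeak <- x[i]
    }
    i <- i + 1
  }
  if (is.null(ev)) ev <- data.frame(x_peak = numeric(0), x_end = numeric(0),
                                    stress_peak = numeric(0),
                                    stress_end = numeric(0))
  ev
}

#' Classify the sliding regime of a trace
#'
#' Stick-slip if at least `min_events` slip events are detected in the
#' trace (see [find_slip_events()]), smooth otherwise.
#'
#' @inheritParams find_slip_events
#' @param min_events minimum number of slips for stick-slip.
#' @param min_travel_nm traces with less stage travel are `"unconverged"`.
#' @return `"stick-slip"`, `"smooth"` or `"unconverged"`.
#' @export
classify_regime <- function(trace, f_drop = 0.5, dx_slip = 1.0,
                            min_drop = 0.5, min_events = 2,
                            min_travel_nm = 1.0) {
  travel <- diff(range(trace$x_stage))
  if (travel < min_travel_nm) return("unconverged")
  ev <- find_slip_events(trace, f_drop, dx_slip, min_drop)
  if (nrow(ev) >= min_events) "stick-slip" else "smooth"
}

#' Critical velocity from a grid of regime labels
#'
#' The transition velocity between stick-slip and smooth sliding: the
#' midpoint between the fastest stick-slip velocity and the slowest smooth
#' velocity, with the bracketing interval.
#'
#' @param v velocities, m/s.
#' @param regime character vector of matching regime labels
#'   (`"stick-slip"` / `"smooth"`).
#' @return list with `v_c` (m/s), `bracket` (length 2), or an error if the
#'   grid does not bracket the transition.
#' @export
critical_velocity <- function(v, regime) {
  stopifnot(length(v) == length(regime))
  vs <- v[regime == "stick-slip"]
  vm <- v[regime == "smooth"]
  if (length(vs) == 0 || length(vm) == 0)
    stop("not bracketed: need both stick-slip and smooth points")
  lo <- max(vs); hi <- min(vm)
  if (hi < lo) stop("not bracketed: regimes are not separated in velocity")
  list(v_c = (lo + hi) / 2, bracket = c(lo, hi))
}
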
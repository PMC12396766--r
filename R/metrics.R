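# Hemodynamic statistics from solved flow fields: wall shear stress (WSS),
# its time average (TAWSS), the oscillatory shear index (OSI), Q-criterion
# vortex fields, centerline metric profiles, flow splits, pressure-drop
# localization, and the TAWSS-diameter correlation.

# --- helpers to reshape axisymmetric fields -------------------------------

.axi_dims <- function(field) {
  list(Nz = field$grid$Nz, Nr = field$grid$Nr)
}

# u at cell centers (Nz x Nr) for one stored phase, using the inlet profile
# for the west face of the first column
.axi_u_centers <- function(field, phase) {
  g <- field$grid
  u <- matrix(field$u[, phase], g$Nz, g$Nr)
  t_ph <- field$times[phase]
  uin <- 2 * field$inlet$v_mean(t_ph) * (1 - g$etac^2)
  uw <- rbind(uin, u[-g$Nz, , drop = FALSE])
  (uw + u) / 2
}

.axi_v_centers <- function(field, phase) {
  g <- field$grid
  v <- matrix(field$v[, phase], g$Nz, g$Nr - 1)
  vlo <- cbind(0, v)    # axis face
  vhi <- cbind(v, 0)    # wall face
  (vlo + vhi) / 2
}

.axi_ring <- function(grid) {
  pi * (grid$etaf[-1]^2 - grid$etaf[-(grid$Nr + 1)]^2)
}

# --- wall shear stress ----------------------------------------------------

#' Wall shear stress records from a solved flow field
#'
#' Evaluates the instantaneous tangential viscous traction
#' `tau = mu * d(u_t)/dn` at every wall sample and stored phase, using a
#' one-sided quadratic (second-order) fit through the no-slip wall and the
#' two nearest velocity samples along the wall normal. For the axisymmetric
#' tube the samples run along the tube wall (one circumferential value per
#' station, signed positive toward the vein); for the planar junction they
#' run along the two side walls of the fistula/vein branch.
#'
#' @param field a `flow_field`.
#' @return a `wall_shear_record`: list with `s_mm` (arc length from the
#'   anastomosis), `tau` (stations x phases matrix, Pa), `times`, `period_s`,
#'   and for planar fields a `wall` label.
#' @export
wall_shear_stress <- function(field) {
  mu <- field$fluid$viscosity
  if (field$grid$topology == "axisymmetric_tube") {
    g <- field$grid
    Nz <- g$Nz; Nr <- g$Nr
    zu <- g$zf[-1]
    Rw <- g$R_zf[-1]; Rpw <- g$Rp_zf[-1]
    slope <- sqrt(1 + Rpw^2)
    d1 <- (1 - g$etac[Nr]) * Rw / slope
    d2 <- (1 - g$etac[Nr - 1]) * Rw / slope
    tau <- matrix(NA_real_, Nz, field$n_store)
    for (ph in seq_len(field$n_store)) {
      u <- matrix(field$u[, ph], Nz, Nr)
      v <- matrix(field$v[, ph], Nz, Nr - 1)
      # v interpolated to u-nodes at the two near-wall eta rows
      v_at <- function(jc) {
        # v faces j-1 and j bracket eta center jc; wall face value 0
        wlo <- if (jc - 1 >= 1) v[, jc - 1] else 0
        whi <- if (jc <= Nr - 1) v[, jc] else 0
        vz <- (wlo + whi) / 2
        (vz + c(vz[-1], vz[Nz])) / 2
      }
      ut1 <- (u[, Nr] + Rpw * v_at(Nr)) / slope
      ut2 <- (u[, Nr - 1] + Rpw * v_at(Nr - 1)) / slope
      tau[, ph] <- mu * (ut1 * d2^2 - ut2 * d1^2) / (d1 * d2 * (d2 - d1))
    }
    rec <- list(s_mm = m_to_mm(zu), tau = tau, times = field$times,
                period_s = field$inlet$period_s)
    class(rec) <- "wall_shear_record"
    return(rec)
  }
  # planar junction: side walls of the branch (x = +-w(y)/2), tangential v
  g <- field$grid
  meta <- field$disc_meta
  vfid <- meta$vfid
  Nx <- g$Nx; Ny <- g$Ny
  h <- g$h
  samples <- list()
  for (j in seq_len(Ny + 1)) {
    yj <- if (j <= Ny) g$yc[j] - h / 2 else g$yc[Ny] + h / 2
    if (yj <= 0) next
    row <- vfid[, j]
    act <- which(row > 0)
    if (!length(act)) next
    iL <- min(act); iR <- max(act)
    if (iR - iL < 3) next
    samples[[length(samples) + 1]] <-
      list(y = yj, wall = "left", v1 = row[iL], v2 = row[iL + 1])
    samples[[length(samples) + 1]] <-
      list(y = yj, wall = "right", v1 = row[iR], v2 = row[iR - 1])
  }
  ns <- length(samples)
  tau <- matrix(NA_real_, ns, field$n_store)
  for (ph in seq_len(field$n_store)) {
    v <- field$v[, ph]
    for (q in seq_len(ns)) {
      sm <- samples[[q]]
      v1 <- v[sm$v1]; v2 <- v[sm$v2]
      tau[q, ph] <- mu * (9 * v1 - v2) / (3 * h)
    }
  }
  rec <- list(s_mm = m_to_mm(vapply(samples, `[[`, numeric(1), "y")),
              wall = vapply(samples, `[[`, character(1), "wall"),
              tau = tau, times = field$times, period_s = field$inlet$period_s)
  class(rec) <- "wall_shear_record"
  rec
}

#' @export
print.wall_shear_record <- function(x, ...) {
  cat(sprintf("wall_shear_record: %d wall samples x %d phases, |tau| max %.3g Pa\n",
              nrow(x$tau), ncol(x$tau), max(abs(x$tau))))
  invisible(x)
}

# cyclic trapezoid time average over one period: values per phase at times
# k*T/n (uniform or not); the wrap segment closes the cycle
.cyclic_time_average <- function(M, times, period) {
  if (is.null(dim(M))) M <- matrix(M, nrow = 1)
  n <- ncol(M)
  if (n < 2) stop("need at least 2 phases spanning the period")
  # segment widths between consecutive phase points, wrapping t_n -> t_1 + T
  w <- diff(c(times[1] - (period - (times[n] - times[1])), times))
  if (any(w <= 0)) stop("phase times must be increasing within one period")
  Mprev <- cbind(M[, n], M[, -n, drop = FALSE])
  rowSums((M + Mprev) / 2 * rep(w, each = nrow(M))) / period
}

#' Time-averaged wall shear stress
#'
#' Trapezoid-rule time average of `|tau|` over the final stored cycle
#' (cyclic closure, arbitrary phase spacing).
#'
#' @param tau wall-shear time series: numeric vector (one sample), a
#'   stations x phases matrix, or a `wall_shear_record`.
#' @param times phase times (taken from the record when given).
#' @param period cycle period in s.
#' @return TAWSS per station (Pa).
#' @export
tawss <- function(tau, times = NULL, period = NULL) {
  if (inherits(tau, "wall_shear_record")) {
    times <- tau$times; period <- tau$period_s; tau <- tau$tau
  }
  if (is.null(dim(tau))) tau <- matrix(tau, nrow = 1)
  if (ncol(tau) < 2) stop("need at least 2 phases")
  as.numeric(.cyclic_time_average(abs(tau), times, period))
}

#' Oscillatory shear index
#'
#' `OSI = (1/2) (1 - |int tau dt| / int |tau| dt)` over one cycle, with the
#' integrals taken componentwise for vector-valued shear (in the planar and
#' axisymmetric reductions tau is the signed wall-tangential traction). OSI
#' is 0 for unidirectional shear, 0.5 for symmetric full reversal, and is
#' defined as 0 (with a warning) where the shear vanishes identically.
#'
#' @param tau numeric vector (one sample over time), stations x phases
#'   matrix, stations x phases x components array, or `wall_shear_record`.
#' @param times,period as in [tawss()].
#' @return OSI per station, in `[0, 0.5]`.
#' @export
osi <- function(tau, times = NULL, period = NULL) {
  if (inherits(tau, "wall_shear_record")) {
    times <- tau$times; period <- tau$period_s; tau <- tau$tau
  }
  if (is.null(dim(tau))) tau <- matrix(tau, nrow = 1)
  if (length(dim(tau)) == 2) tau <- array(tau, dim = c(dim(tau), 1))
  if (dim(tau)[2] < 2) stop("need at least 2 phases")
  ns <- dim(tau)[1]; nc <- dim(tau)[3]
  mean_comp <- sapply(seq_len(nc), function(cc)
    .cyclic_time_average(tau[, , cc, drop = TRUE], times, period))
  mean_comp <- matrix(mean_comp, ns, nc)
  mag <- sqrt(apply(tau^2, c(1, 2), sum))
  denom <- .cyclic_time_average(mag, times, period)
  num <- sqrt(rowSums(mean_comp^2))
  out <- numeric(ns)
  zero <- denom <= .Machine$double.eps
  if (any(zero))
    warning("OSI undefined for identically zero shear; reporting 0")
  out[!zero] <- 0.5 * (1 - num[!zero] / denom[!zero])
  pmin(pmax(out, 0), 0.5)
}

# --- Q-criterion ----------------------------------------------------------

#' Q-criterion on cell-centered velocity fields
#'
#' `Q = (1/2)(||Omega||^2 - ||S||^2)` from the Frobenius norms of the
#' antisymmetric and symmetric parts of the velocity gradient tensor.
#' Positive Q marks rotation-dominated (vortical) regions. In the
#' axisymmetric case the tensor includes the azimuthal strain `v_r / r`.
#'
#' @param u,v cell-centered velocity component matrices.
#' @param dx,dy grid spacings (m).
#' @param r optional matrix of radial coordinates; when given, the
#'   azimuthal strain `v / r` is included (axisymmetric flows).
#' @return matrix of Q values (1/s^2); edges use one-sided differences.
#' @export
q_criterion_field <- function(u, v, dx, dy, r = NULL) {
  ddx <- function(f) {
    n <- nrow(f)
    out <- (rbind(f[-1, , drop = FALSE], f[n, , drop = FALSE]) -
            rbind(f[1, , drop = FALSE], f[-n, , drop = FALSE]))
    out[2:(n - 1), ] <- out[2:(n - 1), ] / (2 * dx)
    out[c(1, n), ] <- out[c(1, n), ] / dx
    out
  }
  ddy <- function(f) t(ddx2(t(f)))
  ddx2 <- function(f) {
    n <- nrow(f)
    out <- (rbind(f[-1, , drop = FALSE], f[n, , drop = FALSE]) -
            rbind(f[1, , drop = FALSE], f[-n, , drop = FALSE]))
    out[2:(n - 1), ] <- out[2:(n - 1), ] / (2 * dy)
    out[c(1, n), ] <- out[c(1, n), ] / dy
    out
  }
  ux <- ddx(u); uy <- ddy(u)
  vx <- ddx(v); vy <- ddy(v)
  S2 <- ux^2 + vy^2 + 0.5 * (uy + vx)^2
  O2 <- 0.5 * (uy - vx)^2
  if (!is.null(r)) S2 <- S2 + (v / r)^2
  0.5 * (O2 - S2)
}

#' Q-criterion of a solved flow field at one phase
#'
#' @param field a `flow_field`.
#' @param phase stored phase index (default: peak systole).
#' @return for axisymmetric fields, a list with `s_mm`, `eta`, and the Q
#'   matrix; for planar fields, a matrix over the grid with `NA` in solid
#'   cells.
#' @export
q_criterion <- function(field, phase = NULL) {
  if (is.null(phase)) phase <- field$peak_idx
  g <- field$grid
  if (g$topology == "axisymmetric_tube") {
    uc <- .axi_u_centers(field, phase)
    vc <- .axi_v_centers(field, phase)
    # physical-space derivatives on the mapped grid: d/dz|r = d/dzeta + a d/deta
    Nz <- g$Nz; Nr <- g$Nr
    dz <- g$dz
    rmat <- outer(g$R_zc, g$etac)
    a <- -outer(g$Rp_zc / g$R_zc, g$etac)
    dzeta <- function(f) {
      out <- rbind(f[2, ] - f[1, ], (f[-(1:2), , drop = FALSE] -
                   f[1:(Nz - 2), , drop = FALSE]) / 2, f[Nz, ] - f[Nz - 1, ])
      out / dz
    }
    deta <- function(f) {
      ec <- g$etac
      out <- f
      out[, 1] <- (f[, 2] - f[, 1]) / (ec[2] - ec[1])
      out[, Nr] <- (f[, Nr] - f[, Nr - 1]) / (ec[Nr] - ec[Nr - 1])
      if (Nr > 2)
        out[, 2:(Nr - 1)] <- (f[, 3:Nr] - f[, 1:(Nr - 2)]) /
          rep(ec[3:Nr] - ec[1:(Nr - 2)], each = Nz)
      out
    }
    Rmat <- matrix(g$R_zc, Nz, Nr)
    du_e <- deta(uc); dv_e <- deta(vc)
    ux <- dzeta(uc) + a * du_e
    vx <- dzeta(vc) + a * dv_e
    uy <- du_e / Rmat
    vy <- dv_e / Rmat
    S2 <- ux^2 + vy^2 + 0.5 * (uy + vx)^2 + (vc / rmat)^2
    O2 <- 0.5 * (uy - vx)^2
    return(list(s_mm = g$s_mm, eta = g$etac, Q = 0.5 * (O2 - S2)))
  }
  # planar: cell-centered velocities on the masked grid
  meta <- field$disc_meta
  ufid <- meta$ufid; vfid <- meta$vfid; cid <- meta$cid
  Nx <- g$Nx; Ny <- g$Ny
  uc <- matrix(NA_real_, Nx, Ny); vc <- matrix(NA_real_, Nx, Ny)
  uvec <- field$u[, phase]; vvec <- field$v[, phase]
  for (i in seq_len(Nx)) for (j in seq_len(Ny)) {
    if (cid[i, j] == 0) next
    idw <- ufid[i, j]; ide <- ufid[i + 1, j]
    uw <- if (idw > 0) uvec[idw] else 0
    ue_ <- if (ide > 0) uvec[ide] else 0
    uc[i, j] <- (uw + ue_) / 2
    ids <- vfid[i, j]; idn <- vfid[i, j + 1]
    vs <- if (ids > 0) vvec[ids] else 0
    vn <- if (idn > 0) vvec[idn] else 0
    vc[i, j] <- (vs + vn) / 2
  }
  Q <- q_criterion_field(ifelse(is.na(uc), 0, uc), ifelse(is.na(vc), 0, vc),
                         g$h, g$h)
  Q[is.na(uc)] <- NA
  Q
}

# --- profiles and summaries ----------------------------------------------

#' Cross-sectional metric profiles along the centerline
#'
#' Per-station cross-sectional maximum and area-weighted average of a field
#' metric (velocity magnitude or pressure at a phase) or of wall statistics
#' (TAWSS, OSI). Stations are grid stations with s = 0 at the anastomosis.
#'
#' @param field a `flow_field` (axisymmetric).
#' @param metric `"velocity"`, `"pressure"`, `"tawss"`, or `"osi"`.
#' @param phase stored phase index for instantaneous metrics (default peak
#'   systole).
#' @param record optional precomputed [wall_shear_stress()] record.
#' @return a `metric_profile` data frame: `s_mm`, `max`, `avg`.
#' @export
metric_profile <- function(field, metric = c("velocity", "pressure", "tawss", "osi"),
                           phase = NULL, record = NULL) {
  metric <- match.arg(metric)
  g <- field$grid
  if (g$topology != "axisymmetric_tube")
    stop("metric profiles are defined along the axisymmetric tube centerline")
  if (metric %in% c("velocity", "pressure")) {
    if (is.null(phase)) phase <- field$peak_idx
    ring <- .axi_ring(g)
    if (metric == "velocity") {
      uc <- .axi_u_centers(field, phase)
      vc <- .axi_v_centers(field, phase)
      f <- sqrt(uc^2 + vc^2)
    } else {
      f <- matrix(field$p[, phase], g$Nz, g$Nr)
    }
    df <- data.frame(s_mm = g$s_mm,
                     max = apply(f, 1, max),
                     avg = as.numeric(f %*% ring) / sum(ring))
  } else {
    if (is.null(record)) record <- wall_shear_stress(field)
    val <- if (metric == "tawss") tawss(record) else osi(record)
    # axisymmetric: a single circumferential wall value per station
    df <- data.frame(s_mm = record$s_mm, max = val, avg = val)
  }
  if (any(df$max < df$avg - 1e-12)) stop("profile max fell below average")
  class(df) <- c("metric_profile", "data.frame")
  df
}

#' Windowed average of a metric profile
#'
#' Arc-length-weighted mean of the `avg` column over `[s_start, s_end]`,
#' e.g. the average TAWSS across the first 4 mm of the fistula.
#'
#' @param profile a `metric_profile`.
#' @param window `c(s_start, s_end)` in mm.
#' @param stat `"avg"` or `"max"`.
#' @return scalar windowed average.
#' @export
windowed_average <- function(profile, window = c(0, 4), stat = "avg") {
  sel <- profile$s_mm >= window[1] - 1e-9 & profile$s_mm <= window[2] + 1e-9
  if (!any(sel)) stop("window contains no stations")
  mean(profile[[stat]][sel])
}

#' Flow split across outflow branches
#'
#' Cycle-averaged flux through each open outflow boundary divided by the
#' cycle-averaged inlet flux. The fractions must sum to 1 within 0.5%
#' (discrete mass conservation), otherwise an error is raised.
#'
#' @param field a `flow_field`.
#' @return named vector of outflow fractions (`AVF` = fistula/vein branch,
#'   plus `DA` for the junction topology).
#' @export
flow_split <- function(field) {
  nc <- field$n_cycles
  qin <- mean(field$flux_in[, nc])
  qout <- mean(field$flux_out[, nc])
  if (all(is.na(field$flux_out2[, nc]))) {
    frac <- c(AVF = qout / qin)
  } else {
    frac <- c(AVF = qout / qin, DA = mean(field$flux_out2[, nc]) / qin)
  }
  if (abs(sum(frac) - 1) > 0.005)
    stop(sprintf("outflow fractions sum to %.4f: mass conservation violated",
                 sum(frac)))
  frac
}

#' Pressure-drop localization along the fistula
#'
#' Fraction of the total anastomosis-to-outlet pressure drop that occurs
#' within `distance_mm` downstream of the anastomosis, from the
#' cross-sectional average pressure at peak systole. Values well above
#' `distance/length` indicate a focal (stenotic) drop.
#'
#' @param field an axisymmetric `flow_field`.
#' @param distance_mm window length downstream of the anastomosis (s = 0).
#' @param phase stored phase (default peak systole).
#' @param s_end end station for the total drop (default: domain end).
#' @return fraction in `[0, 1]`-ish (can exceed 1 with pressure recovery).
#' @export
pressure_drop_localization <- function(field, distance_mm = 1.5, phase = NULL,
                                       s_end = NULL) {
  g <- field$grid
  if (is.null(phase)) phase <- field$peak_idx
  prof <- metric_profile(field, "pressure", phase = phase)
  pfun <- stats::approxfun(prof$s_mm, prof$avg)
  if (is.null(s_end)) s_end <- max(prof$s_mm)
  p0 <- pfun(0); p1 <- pfun(distance_mm); pe <- pfun(s_end)
  if (abs(p0 - pe) < .Machine$double.eps)
    stop("zero total pressure drop over the fistula")
  (p0 - p1) / (p0 - pe)
}

#' Power-law correlation between TAWSS and lumen diameter
#'
#' Least-squares fit of `log(TAWSS) ~ log(d)` on matched stations. Under
#' Poiseuille scaling at constant flow the exponent is -3; stenotic vessels
#' show the same strong inverse relationship.
#'
#' @param tawss_profile data frame with `s_mm` and TAWSS values (column
#'   `avg`, `max`, or `value`).
#' @param diameter_profile a `diameter_profile` (matched by interpolation).
#' @param s_range optional arc-length window for the fit.
#' @return list with `exponent`, `r_squared`, `n`.
#' @export
correlate_tawss_diameter <- function(tawss_profile, diameter_profile,
                                     s_range = NULL) {
  tp <- as.data.frame(tawss_profile)
  val_col <- intersect(c("avg", "value", "max"), names(tp))[1]
  dp <- as.data.frame(diameter_profile)
  if ("branch" %in% names(dp)) dp <- dp[dp$branch %in% c("AVF", "vein"), ]
  d <- stats::approx(dp$s_mm, dp$diameter_mm, xout = tp$s_mm, rule = 1)$y
  w <- tp[[val_col]]
  keep <- is.finite(d) & is.finite(w) & d > 0 & w > 0
  if (!is.null(s_range))
    keep <- keep & tp$s_mm >= s_range[1] & tp$s_mm <= s_range[2]
  if (sum(keep) < 5) stop("need at least 5 matched stations with positive values")
  fit <- stats::lm(log(w[keep]) ~ log(d[keep]))
  # suppressed: summary.lm warns on numerically perfect fits
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(exponent = unname(stats::coef(fit)[2]),
       r_squared = r2,
       n = sum(keep))
}

#' Hemodynamic summary report of a solved run
#'
#' Gathers the per-run quantities: branch flow rates and split fractions,
#' peak velocity, windowed TAWSS/OSI averages over the fistula, Poiseuille
#' resistance of the 4 mm fistula segment, and pressure-drop localization.
#'
#' @param field an axisymmetric `flow_field`.
#' @param profile optional `diameter_profile` for the resistance (defaults
#'   to the analytic profile of the grid's geometry).
#' @param window fistula window in mm for averages.
#' @return a `hemodynamic_report` list.
#' @export
hemodynamic_report <- function(field, profile = NULL, window = c(0, 4)) {
  g <- field$grid
  rec <- wall_shear_stress(field)
  tw <- metric_profile(field, "tawss", record = rec)
  os <- metric_profile(field, "osi", record = rec)
  vel <- metric_profile(field, "velocity")
  if (is.null(profile)) profile <- radius_profile(g$spec, ds = 0.02)
  res <- poiseuille_resistance(profile, mu = field$fluid$viscosity,
                               s_range = window, branch = "AVF")
  nc <- field$n_cycles
  split <- flow_split(field)
  rep <- list(
    flow_ml_min = c(inlet = m3s_to_ml_min(mean(field$flux_in[, nc])),
                    AVF = m3s_to_ml_min(mean(field$flux_out[, nc]))),
    split = split,
    peak_velocity_mm_s = m_to_mm(max(vel$max)),
    tawss_window_pa = windowed_average(tw, window),
    tawss_peak_pa = max(tw$max),
    tawss_peak_s_mm = tw$s_mm[which.max(tw$max)],
    osi_window = windowed_average(os, window),
    osi_peak = max(os$max),
    resistance_pa_s_m3 = res,
    pressure_drop_1p5mm = tryCatch(
      pressure_drop_localization(field, 1.5, s_end = g$spec$fistula$length),
      error = function(e) NA_real_),
    cfl_max = field$cfl_max_observed,
    div_rel_max = field$div_rel_max
  )
  class(rep) <- "hemodynamic_report"
  rep
}

#' @export
print.hemodynamic_report <- function(x, ...) {
  cat("hemodynamic report\n")
  cat(sprintf("  flow: inlet %.3f mL/min, AVF branch %.3f mL/min\n",
              x$flow_ml_min["inlet"], x$flow_ml_min["AVF"]))
  cat(sprintf("  split: %s\n",
              paste(sprintf("%s %.0f%%", names(x$split), 100 * x$split),
                    collapse = ", ")))
  cat(sprintf("  peak velocity %.0f mm/s\n", x$peak_velocity_mm_s))
  cat(sprintf("  TAWSS: %.2f Pa avg over window, peak %.2f Pa at s = %.2f mm\n",
              x$tawss_window_pa, x$tawss_peak_pa, x$tawss_peak_s_mm))
  cat(sprintf("  OSI: %.4f avg, %.3f peak\n", x$osi_window, x$osi_peak))
  cat(sprintf("  Poiseuille resistance (window): %.3g Pa s/m^3\n",
              x$resistance_pa_s_m3))
  if (is.finite(x$pressure_drop_1p5mm))
    cat(sprintf("  pressure drop within 1.5 mm: %.0f%%\n",
                100 * x$pressure_drop_1p5mm))
  invisible(x)
}
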
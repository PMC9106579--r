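# Bulk and surface partition coefficients from surface-relative profiles.

#' Measure bulk, surface and cytosol intensity levels of one granule
#'
#' From the granule-channel profile `g_s,SG(d)` the gradient anchor `d*` is
#' the position of maximal gradient (central differences on the 1-px grid).
#' The surface level `I_s` is the maximum of `g_s,TUB(d)` within +/- 2 px of
#' `d*`; the bulk level `I_g` is the mean of `g_s,TUB` for `d <= -0.39` um,
#' excluding the single most-negative-d entry (the granule centre, which has
#' poor statistics); the cytosol level `I_c` is the mean for
#' `d` in `[0.39, 0.52]` um. Only granules with `R_SG >= 0.59` um and at
#' least three interior entries at `d <= -0.39` um are eligible.
#'
#' @param gs_sg,gs_tub [surface_profile()] tibbles of the granule-marker and
#'   tubulin channels.
#' @param R_um granule effective radius, um.
#' @param pitch pixel pitch, um/px.
#' @param min_radius_um eligibility radius.
#' @param interface_um interface half-width (inner window edge), um.
#' @param cytosol_um outer edge of the cytosol window, um.
#' @param anchor_halfwidth_px half-width of the surface-peak search window
#'   around `d*`, px.
#' @param min_interior_entries minimum interior d-entries required.
#' @return tibble row with `I_s`, `I_g`, `I_c`, `d_star_um`, `eligible` and a
#'   skip reason.
#' @export
measure_levels <- function(gs_sg, gs_tub, R_um, pitch = 0.065,
                           min_radius_um = 0.59, interface_um = 0.39,
                           cytosol_um = 0.52, anchor_halfwidth_px = 2,
                           min_interior_entries = 3) {
  skip <- function(reason) tibble::tibble(
    I_s = NA_real_, I_g = NA_real_, I_c = NA_real_, d_star_um = NA_real_,
    eligible = FALSE, reason = reason)
  if (R_um < min_radius_um) return(skip("radius below eligibility"))
  interior <- which(gs_tub$d_um <= -interface_um + 1e-9)
  if (length(interior) < min_interior_entries)
    return(skip("too few interior entries"))
  # gradient anchor from the granule-marker profile
  gsg <- gs_sg[is.finite(gs_sg$g_s), ]
  if (nrow(gsg) < 3) return(skip("degenerate granule profile"))
  grad <- (dplyr::lead(gsg$g_s) - dplyr::lag(gsg$g_s)) /
    (dplyr::lead(gsg$d_um) - dplyr::lag(gsg$d_um))
  # the granule marker falls from interior to cytosol, so the interface is
  # the point of maximal |slope|
  i_star <- which.max(abs(grad))
  if (!length(i_star) || !is.finite(grad[i_star]))
    return(skip("no gradient maximum"))
  d_star <- gsg$d_um[i_star]
  win <- anchor_halfwidth_px * pitch + 1e-9
  surf <- gs_tub$g_s[abs(gs_tub$d_um - d_star) <= win]
  surf <- surf[is.finite(surf)]
  if (!length(surf)) return(skip("empty surface window"))
  I_s <- max(surf)
  # interior: drop the single most-negative-d entry
  int_d <- gs_tub$d_um[interior]
  drop_i <- interior[which.min(int_d)]
  gi <- gs_tub$g_s[setdiff(interior, drop_i)]
  gi <- gi[is.finite(gi)]
  if (!length(gi)) return(skip("empty interior window"))
  I_g <- mean(gi)
  cy <- gs_tub$g_s[gs_tub$d_um >= interface_um - 1e-9 &
                     gs_tub$d_um <= cytosol_um + 1e-9]
  cy <- cy[is.finite(cy)]
  if (!length(cy)) return(skip("empty cytosol window"))
  I_c <- mean(cy)
  tibble::tibble(I_s = I_s, I_g = I_g, I_c = I_c, d_star_um = d_star,
                 eligible = TRUE, reason = NA_character_)
}

#' Convert intensity levels to partition coefficients and affinities
#'
#' `k_g = I_g / I_c`, `k_s = I_s / I_c`; affinities (k_BT units) are
#' `-dG_g = ln k_g`, `-dG_s = ln k_s`. Granules with non-positive levels are
#' skipped.
#'
#' @param levels tibble from [measure_levels()].
#' @return the tibble augmented with `k_g`, `k_s`, `lnkg`, `lnks`.
#' @export
to_partition_and_affinity <- function(levels) {
  lv <- levels
  bad <- lv$eligible &
    (!is.finite(lv$I_c) | lv$I_c <= 0 | lv$I_g <= 0 | lv$I_s <= 0)
  lv$eligible[bad] <- FALSE
  lv$reason[bad] <- "non-positive intensity level"
  lv$k_g <- ifelse(lv$eligible, lv$I_g / lv$I_c, NA_real_)
  lv$k_s <- ifelse(lv$eligible, lv$I_s / lv$I_c, NA_real_)
  lv$lnkg <- log(lv$k_g)
  lv$lnks <- log(lv$k_s)
  lv
}

# least-squares Gaussian fit to binned counts; falls back to moment estimates
gauss_fit_hist <- function(x, bins = 25) {
  h <- graphics::hist(x, breaks = bins, plot = FALSE)
  df <- data.frame(m = h$mids, c = h$counts)
  mu0 <- mean(x); s0 <- sd(x); A0 <- max(h$counts)
  fit <- tryCatch(
    nls(c ~ A * exp(-(m - mu)^2 / (2 * s^2)), data = df,
        start = list(A = A0, mu = mu0, s = s0)),
    error = function(e) NULL)
  if (is.null(fit)) return(c(mean = mu0, sd = s0, method = NA))
  cf <- coef(fit)
  c(mean = unname(cf["mu"]), sd = abs(unname(cf["s"])), method = 1)
}

#' Cohort statistics of per-granule affinities
#'
#' Histograms of `ln k_g` and `ln k_s` with Gaussian fits (least squares to
#' binned counts), one-sample t-tests of each mean against zero, and the
#' scatter table used by the adsorption-model fit.
#'
#' @param results tibble from [to_partition_and_affinity()] (eligible rows
#'   are used).
#' @param min_granules minimum eligible granules.
#' @return list with `summary` (tibble, one row per affinity), `scatter`
#'   (tibble `lnkg`, `lnks`) and `n`.
#' @export
cohort_statistics <- function(results, min_granules = 10) {
  el <- results[results$eligible & is.finite(results$lnkg) &
                  is.finite(results$lnks), ]
  if (nrow(el) < min_granules)
    stop("need at least ", min_granules, " eligible granules")
  stat_one <- function(v, label) {
    gf <- gauss_fit_hist(v)
    tt <- if (sd(v) > 0) t.test(v, mu = 0) else NULL
    tibble::tibble(
      affinity = label, n = length(v), mean = mean(v), sd = sd(v),
      se = sd(v) / sqrt(length(v)),
      gauss_mean = gf[["mean"]], gauss_sd = gf[["sd"]],
      p_value = if (is.null(tt)) NA_real_ else tt$p.value)
  }
  list(
    summary = dplyr::bind_rows(stat_one(el$lnkg, "bulk (ln k_g)"),
                               stat_one(el$lnks, "surface (ln k_s)")),
    scatter = tibble::tibble(lnkg = el$lnkg, lnks = el$lnks),
    n = nrow(el)
  )
}
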
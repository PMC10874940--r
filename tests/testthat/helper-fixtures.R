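# Shared in-code fixtures; everything is generated, nothing is stored.

# small phantom used by several segmentation tests (~17k in-nidus voxels)
test_phantom <- function(proportions = c(30.9, 52.2, 16.8) * 100 / 99.9,
                         fwhm = 3, seed = 11L, shape = 48L, radius = 16) {
  generate_phantom(phantom_spec(
    grid_shape = shape, nidus_radius = radius,
    target_proportions = proportions, smoothing_fwhm = fwhm, seed = seed))
}

# scalar trilinear interpolation oracle, written independently of
# resample_dose(): direct evaluation of the 8-corner formula at one world
# point; returns 0 outside the grid
trilinear_oracle <- function(vol, grid, point) {
  g <- (point - grid$origin) / grid$spacing   # 0-based continuous index
  d <- dim(vol)
  if (any(g < 0) || any(g > d - 1)) return(0)
  i0 <- pmax(pmin(floor(g), d - 2), 0)
  f <- g - i0
  val <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
    val <- val + w * vol[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
  }
  val
}

# Breslow log partial likelihood for a single covariate, evaluated directly
# from its definition (used as a grid-search oracle for cox_fit)
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    dead <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + sum(beta * x[dead]) -
      length(dead) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# hand-tabulated K=2 log-rank statistic (observed minus expected over
# hypergeometric variance), independent of survival::survdiff
logrank_oracle <- function(time, event, group) {
  g1 <- group == unique(group)[1]
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# exhaustive ROC oracle: sensitivity/specificity at a threshold by counting
roc_point_oracle <- function(scores, labels, threshold) {
  pos <- labels == 1
  c(sensitivity = mean(scores[pos] >= threshold),
    specificity = mean(scores[!pos] < threshold))
}
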
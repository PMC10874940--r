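#' Resample a dose volume onto a target grid
#'
#' Trilinear interpolation in world coordinates, mirroring the first step of
#' the automated segmentation: the planning dose map is interpolated onto the
#' T2-weighted MRI grid. Points falling outside the dose grid receive 0 Gy.
#'
#' @param dose 3-D numeric array of dose values (Gy).
#' @param dose_grid [grid3d()] of the dose array.
#' @param target_shape Integer dimensions of the target grid (length 3).
#' @param target_grid [grid3d()] of the target.
#' @return 3-D numeric array with `dim = target_shape`.
#' @export
resample_dose <- function(dose, dose_grid, target_shape, target_grid) {
  stopifnot(inherits(dose_grid, "grid3d"), inherits(target_grid, "grid3d"))
  dims <- dim(dose)
  if (length(dims) != 3L) stop("dose must be a 3-D array", call. = FALSE)
  target_shape <- rep_len(as.integer(target_shape), 3L)

  # bounding boxes in world coordinates; refuse fully disjoint grids
  lo_s <- dose_grid$origin
  hi_s <- dose_grid$origin + (dims - 1) * dose_grid$spacing
  lo_t <- target_grid$origin
  hi_t <- target_grid$origin + (target_shape - 1) * target_grid$spacing
  if (any(hi_s < lo_t | hi_t < lo_s))
    stop("dose grid and target grid do not overlap", call. = FALSE)

  # continuous (0-based) source index of every target voxel, per axis
  idx <- lapply(1:3, function(a) {
    w <- target_grid$origin[a] + (seq_len(target_shape[a]) - 1) *
      target_grid$spacing[a]
    (w - dose_grid$origin[a]) / dose_grid$spacing[a]
  })
  nt <- prod(target_shape)
  gx <- rep(idx[[1]], times = nt / target_shape[1])
  gy <- rep(rep(idx[[2]], each = target_shape[1]),
            times = target_shape[3])
  gz <- rep(idx[[3]], each = target_shape[1] * target_shape[2])

  inside <- gx >= 0 & gx <= dims[1] - 1 &
    gy >= 0 & gy <= dims[2] - 1 &
    gz >= 0 & gz <= dims[3] - 1
  out <- numeric(nt)
  if (any(inside)) {
    x <- gx[inside]; y <- gy[inside]; z <- gz[inside]
    x0 <- pmin(floor(x), dims[1] - 2); x0 <- pmax(x0, 0)
    y0 <- pmin(floor(y), dims[2] - 2); y0 <- pmax(y0, 0)
    z0 <- pmin(floor(z), dims[3] - 2); z0 <- pmax(z0, 0)
    fx <- x - x0; fy <- y - y0; fz <- z - z0
    at <- function(i, j, k) dose[cbind(i + 1, j + 1, k + 1)]
    v <-
      at(x0,     y0,     z0    ) * (1 - fx) * (1 - fy) * (1 - fz) +
      at(x0 + 1, y0,     z0    ) * fx       * (1 - fy) * (1 - fz) +
      at(x0,     y0 + 1, z0    ) * (1 - fx) * fy       * (1 - fz) +
      at(x0 + 1, y0 + 1, z0    ) * fx       * fy       * (1 - fz) +
      at(x0,     y0,     z0 + 1) * (1 - fx) * (1 - fy) * fz +
      at(x0 + 1, y0,     z0 + 1) * fx       * (1 - fy) * fz +
      at(x0,     y0 + 1, z0 + 1) * (1 - fx) * fy       * fz +
      at(x0 + 1, y0 + 1, z0 + 1) * fx       * fy       * fz
    out[inside] <- v
  }
  dim(out) <- target_shape
  out
}

#' Prescription isodose ROI
#'
#' The region of interest of the segmentation: every voxel whose dose reaches
#' the prescribed margin dose (the prescription isodose volume). The boundary
#' is inclusive (`dose >= margin_dose`).
#'
#' @param dose_on_t2 3-D dose array on the T2 grid (Gy).
#' @param margin_dose Prescribed margin dose (Gy, > 0).
#' @param strict If `TRUE` use a strict `>` comparison instead of `>=`.
#' @return Logical 3-D mask with attribute `n_voxels`.
#' @export
prescription_roi <- function(dose_on_t2, margin_dose, strict = FALSE) {
  if (margin_dose <= 0) stop("margin_dose must be positive", call. = FALSE)
  mask <- if (strict) dose_on_t2 > margin_dose else dose_on_t2 >= margin_dose
  if (!any(mask))
    stop("no voxel reaches the prescribed margin dose", call. = FALSE)
  attr(mask, "n_voxels") <- sum(mask)
  mask
}

#' Fuzzy c-means parameters
#'
#' @param n_clusters Number of clusters (>= 2; 3 tissues by default).
#' @param m Fuzzifier (> 1). At m close to 1 the algorithm approaches hard
#'   k-means; large m drives all memberships towards 1/c.
#' @param tol Convergence threshold on the maximum centroid movement,
#'   expressed as a fraction of the intensity range.
#' @param max_iter Maximum iterations per restart.
#' @param n_init Number of restarts; restart 1 initialises centroids at the
#'   10th/50th/90th intensity percentiles (deterministic), the rest uniformly
#'   at random within the intensity range. The lowest final objective wins.
#' @param seed Integer seed for the random restarts.
#' @return An object of class `fcm_params`.
#' @export
fcm_params <- function(n_clusters = 3L, m = 2, tol = 1e-5, max_iter = 300L,
                       n_init = 5L, seed = 1L) {
  if (n_clusters < 2) stop("n_clusters must be >= 2", call. = FALSE)
  if (m <= 1) stop("fuzzifier m must be > 1", call. = FALSE)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  structure(list(n_clusters = as.integer(n_clusters), m = as.numeric(m),
                 tol = as.numeric(tol), max_iter = as.integer(max_iter),
                 n_init = as.integer(n_init), seed = as.integer(seed)),
            class = "fcm_params")
}

# memberships for 1-D values given centroids; zero-distance points get a
# crisp membership in the (first) coinciding cluster
fcm_memberships <- function(values, centroids, m) {
  d2 <- outer(values, centroids, function(x, c) (x - c)^2)
  zero <- d2 < .Machine$double.xmin
  u <- d2^(-1 / (m - 1))
  u <- u / rowSums(u)
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    u[hit, ] <- 0
    first0 <- apply(zero[hit, , drop = FALSE], 1L, which.max)
    u[cbind(which(hit), first0)] <- 1
  }
  u
}

fcm_objective <- function(values, centroids, u, m) {
  d2 <- outer(values, centroids, function(x, c) (x - c)^2)
  sum(u^m * d2)
}

fcm_single <- function(values, init, m, tol_abs, max_iter) {
  centroids <- init
  objective_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  u <- fcm_memberships(values, centroids, m)
  repeat {
    iter <- iter + 1L
    um <- u^m
    new_c <- colSums(um * values) / colSums(um)
    u <- fcm_memberships(values, new_c, m)
    objective_trace[iter] <- fcm_objective(values, new_c, u, m)
    moved <- max(abs(new_c - centroids))
    centroids <- new_c
    if (moved < tol_abs) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  list(centroids = centroids, membership = u,
       objective = objective_trace[iter], objective_trace = objective_trace,
       iterations = iter, converged = converged)
}

#' Fuzzy c-means clustering of intensities
#'
#' Standard FCM on scalar values: memberships
#' `u_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1))`, centroids the
#' membership^m-weighted means, iterated until the maximum centroid movement
#' drops below `tol` (a fraction of the intensity range) or `max_iter` is
#' reached. Among `n_init` restarts the run with the lowest final objective
#' is returned.
#'
#' @param values Numeric vector of intensities (at least `n_clusters`
#'   distinct values).
#' @param params An [fcm_params()].
#' @return A list of class `fcm_fit`: `centroids` (ascending), `membership`
#'   (n x c matrix, columns in centroid order, rows summing to 1),
#'   `objective`, `objective_trace` of the winning restart, `iterations`,
#'   `converged`.
#' @export
fcm <- function(values, params = fcm_params()) {
  stopifnot(inherits(params, "fcm_params"))
  values <- as.numeric(values)
  if (length(unique(values)) < params$n_clusters)
    stop("degenerate input: fewer distinct values (", length(unique(values)),
         ") than clusters (", params$n_clusters, ")", call. = FALSE)
  rng <- range(values)
  tol_abs <- params$tol * (rng[2] - rng[1])

  inits <- vector("list", params$n_init)
  probs <- seq(0.1, 0.9, length.out = params$n_clusters)
  inits[[1]] <- as.numeric(stats::quantile(values, probs, names = FALSE))
  if (params$n_init > 1L) {
    set.seed(params$seed)
    for (i in 2:params$n_init)
      inits[[i]] <- sort(stats::runif(params$n_clusters, rng[1], rng[2]))
  }
  fits <- lapply(inits, function(init)
    fcm_single(values, init, params$m, tol_abs, params$max_iter))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]

  ord <- order(best$centroids)
  best$centroids <- best$centroids[ord]
  best$membership <- best$membership[, ord, drop = FALSE]
  class(best) <- "fcm_fit"
  best
}

#' Map sorted centroids to tissue classes
#'
#' On T2-weighted MRI fast-flowing blood is darkest (flow void), brain
#' parenchyma intermediate, and CSF brightest, so the lowest centroid is
#' vessel, the middle brain, the highest CSF — regardless of input order.
#'
#' @param centroids Three centroid intensities.
#' @param tol Centroids closer than this are considered tied.
#' @return Named numeric vector `c(vessel =, brain =, csf =)` of centroid
#'   intensities in ascending order.
#' @export
tissue_assignment <- function(centroids, tol = 1e-8) {
  if (length(centroids) != 3L)
    stop("exactly three centroids are required", call. = FALSE)
  s <- sort(as.numeric(centroids))
  if (any(diff(s) <= tol))
    stop("unresolvable tissue ordering: two centroids coincide", call. = FALSE)
  stats::setNames(s, c("vessel", "brain", "csf"))
}

#' Tissue proportions inside the ROI
#'
#' Each ROI voxel is hard-assigned to its maximum-membership class (ties go
#' to the lower tissue class index) and percentages are class counts over the
#' ROI count.
#'
#' @param membership n x 3 membership matrix, columns in ascending-centroid
#'   (vessel, brain, csf) order.
#' @return Named percentages summing to 100.
#' @export
tissue_proportions <- function(membership) {
  if (nrow(membership) == 0L) stop("empty ROI", call. = FALSE)
  hard <- max.col(membership, ties.method = "first")
  100 * c(vessel = mean(hard == 1L), brain = mean(hard == 2L),
          csf = mean(hard == 3L))
}

#' Compactness index
#'
#' The ratio of the vascular proportion to the brain-tissue proportion within
#' the prescription isodose volume; values at or above the cutoff (0.63 by
#' default elsewhere) mark a compact nidus.
#'
#' @param proportions Named percentages with elements `vessel` and `brain`.
#' @return Positive scalar, `vessel / brain`.
#' @export
compactness_index <- function(proportions) {
  v <- proportions[["vessel"]]; b <- proportions[["brain"]]
  if (b <= 0)
    stop("compactness index undefined: brain proportion is zero", call. = FALSE)
  unname(v / b)
}

#' Segment a bAVM nidus within the prescription isodose volume
#'
#' End-to-end automated segmentation: interpolate the dose map onto the T2
#' grid, take the prescription isodose ROI (`dose >= margin_dose`), cluster
#' the ROI intensities into three tissues with fuzzy c-means, map centroids
#' to vessel/brain/CSF by T2 brightness, and report tissue proportions and
#' the compactness index.
#'
#' @param t2 3-D T2-weighted intensity array.
#' @param dose 3-D dose array (Gy).
#' @param margin_dose Prescribed margin dose (Gy).
#' @param params An [fcm_params()].
#' @param t2_grid,dose_grid [grid3d()] descriptors; when the dose shares the
#'   T2 grid the resampling step is an identity.
#' @return An object of class `avm_segmentation`: `proportions`,
#'   `compactness_index`, `roi_voxels`, `centroids` (named, ascending),
#'   `hard_labels` (3-D integer array, 0 outside ROI), `converged`,
#'   `iterations`, `objective`.
#' @export
segment_bavm <- function(t2, dose, margin_dose, params = fcm_params(),
                         t2_grid = grid3d(), dose_grid = t2_grid) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  dose_t2 <- stage("resample_dose",
                   resample_dose(dose, dose_grid, dim(t2), t2_grid))
  roi <- stage("prescription_roi", prescription_roi(dose_t2, margin_dose))
  fit <- stage("fcm", fcm(t2[roi], params))
  cents <- stage("tissue_assignment", tissue_assignment(fit$centroids))
  props <- stage("tissue_proportions", tissue_proportions(fit$membership))
  ci <- stage("compactness_index", compactness_index(props))

  hard <- array(0L, dim = dim(t2))
  hard[roi] <- max.col(fit$membership, ties.method = "first")
  structure(list(proportions = props, compactness_index = ci,
                 roi_voxels = sum(roi), centroids = cents,
                 hard_labels = hard, converged = fit$converged,
                 iterations = fit$iterations, objective = fit$objective),
            class = "avm_segmentation")
}

#' @export
print.avm_segmentation <- function(x, ...) {
  cat(sprintf("bAVM segmentation: %d ROI voxels (%s)\n", x$roi_voxels,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  proportions: vessel %.1f%%, brain %.1f%%, csf %.1f%%\n",
              x$proportions[1], x$proportions[2], x$proportions[3]))
  cat(sprintf("  centroids: %.1f / %.1f / %.1f\n",
              x$centroids[1], x$centroids[2], x$centroids[3]))
  cat(sprintf("  compactness index: %.3f\n", x$compactness_index))
  invisible(x)
}
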
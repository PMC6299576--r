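#' Synthetic chest-CT phantom specification
#'
#' Parameters of the phantom generator. The phantom emulates the
#' statistical structure that density scoring relies on: a body ellipsoid
#' of soft tissue in outside air, two lung ellipsoids whose parenchymal
#' voxels follow a sharp Gaussian peak near -850 HU, a small fraction of
#' bright vessel-like tubes producing the right tail of the histogram, and
#' disease as mid-density lesion blobs that replace parenchymal voxels.
#' Inspiration level is modelled as an affine transform of the lung
#' voxels (shift and spread about the lung mean).
#'
#' @param shape Grid dimensions (voxels), default `c(96, 96, 96)`.
#' @param spacing Voxel spacing (mm), default 3 mm isotropic.
#' @param body_hu Soft-tissue HU of the body ellipsoid (+40).
#' @param air_hu Background air HU (-1000).
#' @param parenchyma_mean,parenchyma_sd Gaussian parenchyma distribution
#'   (HU), default -850 +/- 60 (inspiratory adult lung).
#' @param vessel_fraction Fraction of lung voxels replaced by vessel tubes
#'   (default 0.03).
#' @param vessel_hu,vessel_sd Gaussian vessel HU distribution, default
#'   +30 +/- 20 (blood/soft tissue; the dispersion keeps the histogram
#'   right tail smooth instead of a one-bin spike).
#' @param lesion_fraction Fraction `f` of lung voxels replaced by lesion
#'   blobs, in `[0, 0.3]`; default 0 (healthy).
#' @param lesion_mean,lesion_sd Gaussian lesion HU distribution, default
#'   -150 +/- 100 (mid-density mucus plugging / consolidation-like).
#' @param lesion_bias_lower Probability that a lesion blob is seeded in
#'   the lower half of a lung; 0.5 = unbiased, 1 = all lower.
#' @param inspiration_shift Additive HU shift applied to lung voxels
#'   (expiration shifts the histogram toward higher density).
#' @param inspiration_scale Multiplicative spread scale about the lung
#'   mean (> 0; expiration flattens the histogram).
#' @param noise_sd Optional additive Gaussian scanner noise (HU) over the
#'   whole volume; 0 disables.
#' @param trachea Include a narrow air column (trachea-like) in the upper
#'   mediastinum.
#' @param body_semi,lung_semi Ellipsoid semi-axes as fractions of the grid
#'   extent per axis.
#' @param lung_offset_x Lateral lung-center offset as a fraction of the
#'   x extent.
#' @param seed Integer seed; every random element of the phantom flows
#'   from it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(96, 96, 96), spacing = c(3, 3, 3),
                         body_hu = 40, air_hu = -1000,
                         parenchyma_mean = -850, parenchyma_sd = 60,
                         vessel_fraction = 0.03, vessel_hu = 30,
                         vessel_sd = 20, lesion_fraction = 0, lesion_mean = -150,
                         lesion_sd = 100, lesion_bias_lower = 0.5,
                         inspiration_shift = 0, inspiration_scale = 1,
                         noise_sd = 0, trachea = FALSE,
                         body_semi = c(0.44, 0.37, 0.46),
                         lung_semi = c(0.17, 0.25, 0.36),
                         lung_offset_x = 0.21, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L)) {
    abort("`shape` must be 3 dimensions of at least 8 voxels.",
          class = "lungdens_validation_error")
  }
  hu <- c(body_hu, air_hu, parenchyma_mean, lesion_mean, vessel_hu)
  if (any(!is.finite(hu))) {
    abort("All HU parameters must be finite.",
          class = "lungdens_validation_error")
  }
  if (vessel_fraction < 0 || vessel_fraction > 1 ||
      lesion_fraction < 0 || lesion_fraction > 1 ||
      lesion_fraction + vessel_fraction >= 1) {
    abort("Fractions must lie in [0, 1] with lesion + vessel fraction < 1.",
          class = "lungdens_validation_error")
  }
  if (lesion_fraction > 0.3) {
    abort("`lesion_fraction` above 0.3 is outside the supported range.",
          class = "lungdens_validation_error")
  }
  if (inspiration_scale <= 0) {
    abort("`inspiration_scale` must be > 0.",
          class = "lungdens_validation_error")
  }
  if (lesion_bias_lower < 0 || lesion_bias_lower > 1) {
    abort("`lesion_bias_lower` must lie in [0, 1].",
          class = "lungdens_validation_error")
  }
  structure(list(
    shape = shape, spacing = as.numeric(spacing), body_hu = body_hu,
    air_hu = air_hu, parenchyma_mean = parenchyma_mean,
    parenchyma_sd = parenchyma_sd, vessel_fraction = vessel_fraction,
    vessel_hu = vessel_hu, vessel_sd = vessel_sd, lesion_fraction = lesion_fraction,
    lesion_mean = lesion_mean, lesion_sd = lesion_sd,
    lesion_bias_lower = lesion_bias_lower,
    inspiration_shift = inspiration_shift,
    inspiration_scale = inspiration_scale, noise_sd = noise_sd,
    trachea = isTRUE(trachea), body_semi = body_semi,
    lung_semi = lung_semi, lung_offset_x = lung_offset_x,
    seed = as.integer(seed)), class = "phantom_spec")
}

# Evaluate code with a locally seeded RNG, restoring the caller's stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

ellipsoid_mask <- function(shape, semi, center_frac = c(0, 0, 0)) {
  u <- lapply(1:3, function(ax) {
    (seq_len(shape[ax]) - (shape[ax] + 1) / 2) / shape[ax] - center_frac[ax]
  })
  q <- outer(outer((u[[1]] / semi[1])^2, (u[[2]] / semi[2])^2, `+`),
             (u[[3]] / semi[3])^2, `+`)
  q <= 1
}

ball_offsets_vox <- function(r) {
  g <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
  g[rowSums(g^2) <= r^2 + 1e-9, , drop = FALSE]
}

in_bounds <- function(coords, shape) {
  coords[, 1] >= 1 & coords[, 1] <= shape[1] &
  coords[, 2] >= 1 & coords[, 2] <= shape[2] &
  coords[, 3] >= 1 & coords[, 3] <= shape[3]
}

coords_to_lin <- function(coords, shape) {
  (coords[, 1]) + shape[1] * (coords[, 2] - 1L) +
    shape[1] * shape[2] * (coords[, 3] - 1L)
}

# Grow tube- or blob-shaped structures inside the lung until `target`
# voxels are marked; the last structure is trimmed so the count is exact.
grow_structures <- function(target, lung_lin, lung_coords, shape, eligible,
                            sample_center, make_coords) {
  marked <- logical(length(eligible))  # indexed like lung_lin
  lin_to_pos <- new.env(hash = TRUE)   # not used; kept simple via match
  total <- 0L
  out_lin <- integer(0)
  guard <- 0L
  while (total < target && guard < 10000L) {
    guard <- guard + 1L
    ci <- sample_center()
    coords <- make_coords(lung_coords[ci, ])
    coords <- coords[in_bounds(coords, shape), , drop = FALSE]
    if (nrow(coords) == 0L) next
    lin <- unique(coords_to_lin(coords, shape))
    pos <- match(lin, lung_lin)
    pos <- pos[!is.na(pos)]
    pos <- pos[eligible[pos] & !marked[pos]]
    if (length(pos) == 0L) next
    excess <- total + length(pos) - target
    if (excess > 0L) pos <- pos[seq_len(length(pos) - excess)]
    marked[pos] <- TRUE
    total <- total + length(pos)
  }
  which(marked)
}

#' Generate a synthetic chest-CT phantom with ground truth
#'
#' Builds the phantom described by a [phantom_spec()]: a soft-tissue body
#' ellipsoid in outside air, two lung ellipsoids with Gaussian parenchyma,
#' vessel-like tubes (fixed bright HU) and lesion blobs (mid-density
#' Gaussian) replacing exact fractions of the lung voxels, then the
#' inspiration transform and optional scanner noise. All randomness flows
#' from `spec$seed`; the same spec reproduces the volume bit for bit.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (a [ct_volume()]), `mask` (truth
#'   [lung_mask()], regions `right`/`left`), and `truth`: realized lesion
#'   and vessel voxel counts and per-region lesion fractions (whole,
#'   upper, lower, right, left; upper/lower via the per-lung
#'   volume-halving plane), plus the spec.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(48, 48, 48),
#'                                     lesion_fraction = 0.05, seed = 2))
#' ph$truth$lesion_fraction
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  with_local_seed(spec$seed, {
    body <- ellipsoid_mask(shape, spec$body_semi)
    right <- ellipsoid_mask(shape, spec$lung_semi,
                            c(-spec$lung_offset_x, 0, 0))
    left <- ellipsoid_mask(shape, spec$lung_semi,
                           c(spec$lung_offset_x, 0, 0))
    if (any(right & left)) {
      abort("Lung ellipsoids overlap; reduce `lung_semi` or increase `lung_offset_x`.",
            class = "lungdens_validation_error")
    }
    if (any((right | left) & !body)) {
      abort("Lung ellipsoids do not fit inside the body ellipsoid.",
            class = "lungdens_validation_error")
    }
    lung <- right | left
    n_lung <- sum(lung)
    lung_lin <- which(lung)
    lung_coords <- which(lung, arr.ind = TRUE)

    vox <- array(spec$air_hu, shape)
    vox[body] <- spec$body_hu
    vox[lung] <- rnorm(n_lung, spec$parenchyma_mean, spec$parenchyma_sd)

    # vessel-like tubes: random segments, radius 1-3 voxels
    eligible <- rep(TRUE, n_lung)
    vessel_pos <- integer(0)
    v_target <- round(spec$vessel_fraction * n_lung)
    if (v_target > 0) {
      tube_len <- max(4L, round(0.5 * min(shape)))
      vessel_pos <- grow_structures(
        v_target, lung_lin, lung_coords, shape, eligible,
        sample_center = function() sample.int(n_lung, 1L),
        make_coords = function(c0) {
          dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
          r <- sample(1:3, 1L)
          t <- seq(-tube_len / 2, tube_len / 2, by = 0.5)
          centers <- unique(round(cbind(c0[1] + t * dir[1],
                                        c0[2] + t * dir[2],
                                        c0[3] + t * dir[3])))
          off <- ball_offsets_vox(r)
          ii <- rep(seq_len(nrow(centers)), each = nrow(off))
          jj <- rep(seq_len(nrow(off)), times = nrow(centers))
          centers[ii, , drop = FALSE] + off[jj, , drop = FALSE]
        })
      vox[lung_lin[vessel_pos]] <-
        rnorm(length(vessel_pos), spec$vessel_hu, spec$vessel_sd)
    }

    # lesion blobs: random spheres on parenchymal (non-vessel) voxels
    lesion_pos <- integer(0)
    l_target <- round(spec$lesion_fraction * n_lung)
    if (l_target > 0) {
      eligible[vessel_pos] <- FALSE
      z_cut <- median(lung_coords[, 3])
      lower_set <- which(lung_coords[, 3] < z_cut)
      upper_set <- which(lung_coords[, 3] >= z_cut)
      lesion_pos <- grow_structures(
        l_target, lung_lin, lung_coords, shape, eligible,
        sample_center = function() {
          pool <- if (runif(1) < spec$lesion_bias_lower) lower_set else upper_set
          pool[sample.int(length(pool), 1L)]
        },
        make_coords = function(c0) {
          r <- sample(2:5, 1L)
          off <- ball_offsets_vox(r)
          cbind(c0[1] + off[, 1], c0[2] + off[, 2], c0[3] + off[, 3])
        })
      vox[lung_lin[lesion_pos]] <-
        rnorm(length(lesion_pos), spec$lesion_mean, spec$lesion_sd)
    }

    # inspiration-level transform (affine about the lung mean)
    if (spec$inspiration_shift != 0 || spec$inspiration_scale != 1) {
      mld <- mean(vox[lung_lin])
      vox[lung_lin] <- mld + spec$inspiration_scale * (vox[lung_lin] - mld) +
        spec$inspiration_shift
    }
    if (spec$noise_sd > 0) {
      vox <- vox + array(rnorm(length(vox), 0, spec$noise_sd), shape)
    }

    if (spec$trachea) {
      # narrow air column in the upper mediastinum, enclosed by the body
      cx <- (shape[1] + 1) / 2; cy <- (shape[2] + 1) / 2
      rad <- max(1L, round(0.02 * shape[1]))
      zs <- seq.int(round(shape[3] * 0.55), round(shape[3] * 0.93))
      xr <- seq.int(round(cx) - rad, round(cx) + rad)
      yr <- seq.int(round(cy) - rad, round(cy) + rad)
      tr <- as.matrix(expand.grid(x = xr, y = yr, z = zs))
      keep <- (tr[, 1] - cx)^2 + (tr[, 2] - cy)^2 <= rad^2
      tr <- tr[keep, , drop = FALSE]
      lin <- coords_to_lin(tr, shape)
      lin <- lin[body[lin] & !lung[lin]]
      vox[lin] <- spec$air_hu + 10
    }

    labels <- array(0L, shape)
    labels[right] <- 1L
    labels[left] <- 2L
    mask <- lung_mask(labels, c(right = 1L, left = 2L),
                      spacing = spec$spacing)

    lesion_flag <- logical(n_lung)
    lesion_flag[lesion_pos] <- TRUE
    truth <- phantom_truth(spec, lung_coords, labels, lung_lin, lesion_flag,
                           length(vessel_pos))
    vol <- ct_volume(vox, spacing = spec$spacing)
    list(volume = vol, mask = mask, truth = truth)
  })
}

phantom_truth <- function(spec, lung_coords, labels, lung_lin, lesion_flag,
                          n_vessel) {
  n_lung <- nrow(lung_coords)
  side <- labels[lung_lin]                  # 1 = right, 2 = left
  upper <- logical(n_lung)
  for (s in 1:2) {
    sel <- side == s
    if (!any(sel)) next
    zs <- lung_coords[sel, 3]
    counts <- tabulate(zs, nbins = max(zs))
    from_top <- rev(cumsum(rev(counts)))
    z_cut <- max(which(from_top >= 0.5 * sum(counts)))
    upper[sel] <- zs >= z_cut
  }
  frac <- function(sel) {
    if (!any(sel)) return(NA_real_)
    sum(lesion_flag[sel]) / sum(sel)
  }
  list(
    n_lung_voxels = n_lung,
    n_lesion_voxels = sum(lesion_flag),
    n_vessel_voxels = n_vessel,
    lesion_fraction = list(
      whole = frac(rep(TRUE, n_lung)), upper = frac(upper),
      lower = frac(!upper), right = frac(side == 1L),
      left = frac(side == 2L)),
    vessel_fraction = n_vessel / n_lung,
    spec = spec)
}

#' Apply an inspiration-level transform to the lung voxels
#'
#' Expiration (or an incomplete breath hold) shifts the lung density
#' histogram toward higher HU and flattens it. This is modelled as an
#' affine transform of the masked voxels about the lung mean:
#' `v -> MLD + a * (v - MLD) + shift`. Voxels outside the mask are
#' untouched. MLD moves by exactly `shift`; SD is multiplied by exactly
#' `a`; skewness and kurtosis are unchanged — which is why
#' histogram-adapted thresholds are invariant to this transform.
#'
#' @param vol A [ct_volume()].
#' @param mask A [lung_mask()] on the same grid.
#' @param shift Additive HU shift.
#' @param scale Spread scale `a > 0`.
#' @return A new [ct_volume()].
#' @export
apply_inspiration <- function(vol, mask, shift = 0, scale = 1) {
  check_alignment(vol, mask)
  if (!is.finite(scale) || scale <= 0) {
    abort("`scale` must be > 0.", class = "lungdens_validation_error")
  }
  if (shift == 0 && scale == 1) return(vol)  # exact identity
  sel <- mask$labels > 0L
  v <- vol$voxels
  mld <- mean(v[sel])
  v[sel] <- mld + scale * (v[sel] - mld) + shift
  ct_volume(v, spacing = vol$spacing, origin = vol$origin, axes = vol$axes)
}

#' Generate a synthetic cohort with surrogate spirometry
#'
#' Samples `n` lesion burdens uniformly from `f_range`, assigns each
#' phantom its own derived seed, and generates surrogate spirometry as
#' `intercept - slope * f + N(0, noise_sd)`, clamped to `(0, 130]`
#' percent predicted (FEV1 and FVC with independent noise draws). The
#' cohort table is fully reproducible from `seed`.
#'
#' @param n Number of subjects (>= 3).
#' @param f_range Lesion-fraction interval, e.g. `c(0, 0.15)`.
#' @param spiro Named vector `c(intercept, slope, noise_sd)`; default
#'   `c(100, 300, 5)` (%pred per unit lesion fraction).
#' @param seed Integer master seed.
#' @param base_spec Template [phantom_spec()]; per-subject specs override
#'   its `lesion_fraction` and `seed`.
#' @return Tibble `(id, lesion_fraction, fev1, fvc, phantom_seed)` with a
#'   `specs` attribute holding each subject's [phantom_spec()].
#' @export
#' @examples
#' coh <- generate_cohort(5, c(0, 0.15), seed = 42,
#'                        base_spec = phantom_spec(shape = c(48, 48, 48)))
#' coh
generate_cohort <- function(n, f_range = c(0, 0.15),
                            spiro = c(intercept = 100, slope = 300,
                                      noise_sd = 5),
                            seed = 1L, base_spec = phantom_spec()) {
  if (n < 3L) {
    abort("A cohort needs n >= 3 subjects.",
          class = "lungdens_validation_error")
  }
  if (length(f_range) != 2L || f_range[2] < f_range[1] ||
      f_range[1] < 0 || f_range[2] > 0.3) {
    abort("`f_range` must be an interval inside [0, 0.3].",
          class = "lungdens_validation_error")
  }
  if (f_range[2] == f_range[1]) {
    abort("Degenerate `f_range`: lower and upper bound are equal.",
          class = "lungdens_validation_error")
  }
  spiro <- as.list(spiro)
  with_local_seed(seed, {
    f <- runif(n, f_range[1], f_range[2])
    ph_seed <- sample.int(2147483646L, n)
    clamp <- function(x) pmin(130, pmax(0.1, x))
    fev1 <- clamp(spiro$intercept - spiro$slope * f +
                    rnorm(n, 0, spiro$noise_sd))
    fvc <- clamp(spiro$intercept - spiro$slope * f +
                   rnorm(n, 0, spiro$noise_sd))
    specs <- lapply(seq_len(n), function(i) {
      sp <- base_spec
      sp$lesion_fraction <- f[i]
      sp$seed <- ph_seed[i]
      sp
    })
    out <- tibble(id = sprintf("P%03d", seq_len(n)), lesion_fraction = f,
                  fev1 = fev1, fvc = fvc, phantom_seed = ph_seed)
    attr(out, "specs") <- specs
    out
  })
}

#' Score every phantom of a synthetic cohort
#'
#' Runs the scoring pipeline over a [generate_cohort()] table: each
#' phantom is generated from its spec, the truth mask (or a fresh
#' segmentation) is used, whole-lung histogram features and the threshold
#' suite are computed, plus upper/lower scores under `regional_spec`.
#'
#' @param cohort Output of [generate_cohort()] (must carry its `specs`
#'   attribute).
#' @param specs Threshold suite for whole-lung scores.
#' @param regional_spec Single spec for the upper/lower comparison.
#' @param segment Use [segment_lungs()] instead of the truth mask.
#' @return The cohort tibble joined with feature columns (`mld`, `mode`,
#'   `sd`, `skewness`, `kurtosis`) and one `score_<spec>` column per
#'   threshold, plus `upper_score` and `lower_score`.
#' @export
score_cohort <- function(cohort, specs = default_threshold_suite(),
                         regional_spec = threshold_adapted("MLD", k = 1),
                         segment = FALSE) {
  spec_list <- attr(cohort, "specs")
  if (is.null(spec_list)) {
    abort("`cohort` lacks its `specs` attribute; use generate_cohort().",
          class = "lungdens_validation_error")
  }
  rows <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    ph <- generate_phantom(spec_list[[i]])
    mask <- if (segment) segment_lungs(ph$volume) else ph$mask
    split <- split_upper_lower(mask)
    feats <- compute_features(ph$volume, mask, "whole")
    suite <- score_suite(ph$volume, mask, specs, feats = feats)
    reg <- regional_scores(ph$volume, split, regional_spec)
    wide <- stats::setNames(as.list(suite$score),
                            paste0("score_", suite$spec))
    tibble(id = cohort$id[i], mld = feats$mld, mode = feats$mode,
           sd = feats$sd, skewness = feats$skewness,
           kurtosis = feats$kurtosis, !!!wide,
           upper_score = reg$score[reg$region == "upper"],
           lower_score = reg$score[reg$region == "lower"])
  })
  left_join(cohort, rows, by = "id")
}
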
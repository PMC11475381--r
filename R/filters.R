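#' Filter settings for the per-slice pre-processing chain
#'
#' Defaults follow the standard CCTA settings: non-local means strength of
#' twice the estimated noise SD with 5 px template and 7 px search windows,
#' Frangi sensitivities alpha = beta = 0.5 and gamma = 15, a contour-area
#' threshold of 900 voxels, and grey-intensity thresholds 125-145 in steps
#' of 5 (the multi-threshold copies that are unioned after clustering).
#'
#' `frangi_scales` are the Gaussian scales (in px) of the vesselness filter;
#' 1-6 px covers coronary diameters at ~0.458 mm in-plane spacing.
#' `frangi_cutoff` gates candidate voxels on the vesselness response before
#' grey thresholding (the vesselness score is in \[0, 1\]); it is kept low
#' so vessels crossing the slice plane, which appear as small blobs rather
#' than ridges, survive the blob-suppression term.
#'
#' @param nlm_strength non-local means strength as a multiple of the noise SD.
#' @param nlm_template template window size in px (odd).
#' @param nlm_search search window size in px (odd).
#' @param frangi_alpha,frangi_beta,frangi_gamma Frangi sensitivities.
#' @param frangi_scales Gaussian scales in px.
#' @param frangi_cutoff vesselness gate in \[0, 1\].
#' @param area_threshold contour-area threshold in voxels; connected
#'   components strictly larger are removed.
#' @param grey_thresholds ascending grey-intensity thresholds in \[0, 255\].
#' @return an object of class `filter_params`.
#' @export
filter_params <- function(nlm_strength = 2, nlm_template = 5, nlm_search = 7,
                          frangi_alpha = 0.5, frangi_beta = 0.5,
                          frangi_gamma = 15, frangi_scales = 1:6,
                          frangi_cutoff = 0.05,
                          area_threshold = 900,
                          grey_thresholds = seq(125, 145, by = 5)) {
  p <- list(nlm_strength = nlm_strength, nlm_template = as.integer(nlm_template),
            nlm_search = as.integer(nlm_search), frangi_alpha = frangi_alpha,
            frangi_beta = frangi_beta, frangi_gamma = frangi_gamma,
            frangi_scales = as.numeric(frangi_scales),
            frangi_cutoff = frangi_cutoff,
            area_threshold = area_threshold,
            grey_thresholds = sort(as.numeric(grey_thresholds)))
  num <- unlist(p[c("nlm_strength", "nlm_template", "nlm_search", "frangi_alpha",
                    "frangi_beta", "frangi_gamma", "area_threshold")])
  if (any(num <= 0)) stop("all filter parameters must be positive")
  if (any(p$grey_thresholds < 0) || any(p$grey_thresholds > 255))
    stop("grey_thresholds must lie in [0, 255]")
  structure(p, class = "filter_params")
}

#' Estimate the Gaussian noise SD of a slice
#'
#' Wavelet-based estimator: the median absolute value of the diagonal
#' (HH) Haar detail coefficients divided by the 0.6745 normal quantile
#' (Donoho's robust estimator).  Assumes additive Gaussian noise.
#'
#' @param slice 2D numeric matrix.
#' @return estimated noise SD (>= 0), in intensity units.
#' @export
estimate_noise_sigma <- function(slice) {
  slice <- as.matrix(slice)
  nr <- nrow(slice); nc <- ncol(slice)
  if (nr < 2 || nc < 2) stop("slice must be at least 2 x 2")
  i <- seq(1, nr - nr %% 2, by = 2)
  j <- seq(1, nc - nc %% 2, by = 2)
  a <- slice[i, j, drop = FALSE]
  b <- slice[i + 1, j, drop = FALSE]
  cc <- slice[i, j + 1, drop = FALSE]
  d <- slice[i + 1, j + 1, drop = FALSE]
  hh <- (a - b - cc + d) / 2
  stats::median(abs(hh)) / 0.6745
}

#' Non-local means de-noising of one slice
#'
#' Averages pixels over the search window weighted by template-patch
#' similarity, which removes Gaussian noise while preserving distinct
#' textures.  The filter strength is `params$nlm_strength * sigma`.
#'
#' @param slice 2D numeric matrix.
#' @param sigma noise SD (see [estimate_noise_sigma()]).
#' @param params a [filter_params()].
#' @return de-noised slice, same shape.
#' @export
denoise_slice <- function(slice, sigma, params = filter_params()) {
  stopifnot(sigma >= 0)
  cpp_nlm_denoise(as.matrix(slice), params$nlm_strength * sigma, sigma,
                  params$nlm_template, params$nlm_search)
}

#' Frangi vesselness of one slice
#'
#' Hessian-eigenvalue vesselness for bright tubular structures, maximised
#' over the Gaussian scales in `params$frangi_scales`.  In 2D the
#' blob-deviation term uses beta and the structure term gamma; scores are
#' in \[0, 1\] with ridges near 1 and flat background at 0.
#'
#' @param slice 2D numeric matrix.
#' @param params a [filter_params()].
#' @return matrix of vesselness scores (>= 0).
#' @export
vesselness_filter <- function(slice, params = filter_params()) {
  slice <- as.matrix(slice)
  beta2 <- 2 * params$frangi_beta^2
  gamma2 <- 2 * params$frangi_gamma^2
  best <- matrix(0, nrow(slice), ncol(slice))
  for (s in params$frangi_scales) {
    h <- cpp_hessian2d(slice, s)
    # eigenvalues of [[hxx, hxy], [hxy, hyy]]
    tr <- (h$hxx + h$hyy) / 2
    disc <- sqrt(pmax(((h$hxx - h$hyy) / 2)^2 + h$hxy^2, 0))
    l1 <- tr + disc
    l2 <- tr - disc
    # order by |l1| <= |l2|
    swap <- abs(l1) > abs(l2)
    tmp <- l1[swap]; l1[swap] <- l2[swap]; l2[swap] <- tmp
    rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
    s2 <- l1^2 + l2^2
    v <- exp(-rb2 / beta2) * (1 - exp(-s2 / gamma2))
    # bright structures only; the tolerance absorbs convolution round-off
    # so structureless (constant) regions score exactly zero
    v[l2 >= -1e-10 * max(1, max(abs(slice)))] <- 0
    best <- pmax(best, v)
  }
  best
}

#' Binary thresholding with contour-area removal
#'
#' Converts pixels with grey intensity above `threshold` to foreground and
#' removes connected components (8-connectivity) whose area is strictly
#' larger than `area_threshold`, which discards structures larger than a
#' coronary cross-section (heart chambers, aorta).
#'
#' @param slice 2D numeric matrix of grey intensities.
#' @param threshold grey-intensity threshold in \[0, 255\].
#' @param area_threshold maximum surviving component area, in voxels.
#' @return logical matrix.
#' @export
binarize_and_filter <- function(slice, threshold, area_threshold = 900) {
  stopifnot(threshold >= 0, threshold <= 255)
  mask <- as.matrix(slice) > threshold
  if (!any(mask)) return(mask)
  lab <- cpp_label2d(mask)
  sizes <- tabulate(lab[lab > 0])
  big <- which(sizes > area_threshold)
  if (length(big)) mask[lab %in% big] <- FALSE
  mask
}

#' Run the de-noising and vesselness chain over a volume
#'
#' Applies, per slice, noise estimation, non-local means de-noising and the
#' Frangi filter.  The result holds both the de-noised grey volume and the
#' vesselness volume; thresholding happens per grey-intensity copy in
#' [candidate_mask()].
#'
#' @param vol an [image_volume()].
#' @param params a [filter_params()].
#' @return list with `denoised` and `vesselness` [image_volume()]s and the
#'   per-slice `sigma` estimates.
#' @export
preprocess_volume <- function(vol, params = filter_params()) {
  stopifnot(inherits(vol, "image_volume"))
  d <- dim(vol$voxels)
  den <- array(0, d)
  ves <- array(0, d)
  sig <- numeric(d[3])
  for (k in seq_len(d[3])) {
    sl <- vol$voxels[, , k]
    sig[k] <- estimate_noise_sigma(sl)
    dn <- denoise_slice(sl, sig[k], params)
    den[, , k] <- dn
    ves[, , k] <- vesselness_filter(dn, params)
  }
  list(denoised = image_volume(den, vol$spacing, vol$origin),
       vesselness = image_volume(ves, vol$spacing, vol$origin),
       sigma = sig)
}

#' Candidate coronary voxels at one grey threshold
#'
#' Thresholds the de-noised grey volume at `threshold`, gated by the
#' vesselness response (`params$frangi_cutoff`), and removes in-plane
#' connected components larger than the contour-area threshold.
#'
#' @param pre result of [preprocess_volume()].
#' @param threshold grey-intensity threshold.
#' @param params a [filter_params()].
#' @return a [binary_volume()].
#' @export
candidate_mask <- function(pre, threshold, params = filter_params()) {
  den <- pre$denoised
  d <- dim(den$voxels)
  mask <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    sl <- den$voxels[, , k]
    gated <- sl
    gated[pre$vesselness$voxels[, , k] < params$frangi_cutoff] <- 0
    mask[, , k] <- binarize_and_filter(gated, threshold, params$area_threshold)
  }
  binary_volume(mask, den$spacing, den$origin, threshold_used = threshold)
}
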
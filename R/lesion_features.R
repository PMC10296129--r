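# Lesion-derived features: lesion volume and the voxel-based lesion-symptom
# mapping (VLSM) mean-Z score computed from binary masks and a behavioural
# score.

#' Construct a binary lesion mask
#'
#' @param data 3D array of 0/1 (or logical) voxels; at least one lesioned
#'   voxel.
#' @param voxel_size numeric vector of 3 voxel dimensions in mm.
#' @param space free-text space tag (e.g. `"MNI"`, `"synthetic"`).
#' @return object of class `lesion_mask`.
#' @export
lesion_mask <- function(data, voxel_size, space = "unspecified") {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("mask must be a 3D array", call. = FALSE)
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1))) stop("mask values must be 0/1", call. = FALSE)
  if (sum(data) < 1) stop("mask has no lesioned voxels", call. = FALSE)
  if (missing(voxel_size) || length(voxel_size) != 3L ||
      any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("voxel_size must be 3 positive lengths (mm)", call. = FALSE)
  }
  structure(list(data = array(as.integer(data), dim = dim(data)),
                 voxel_size = as.numeric(voxel_size), space = space),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %s grid, %.3g cc lesioned, space '%s'\n",
              paste(dim(x$data), collapse = "x"), lesion_volume(x), x$space))
  invisible(x)
}

#' Lesion volume in cubic centimetres
#'
#' Lesioned-voxel count times voxel volume, converted from mm^3 to cc.
#'
#' @param mask a [lesion_mask()].
#' @return volume in cc.
#' @export
lesion_volume <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  sum(mask$data) * prod(mask$voxel_size) / 1000
}

#' Minimum lesion-overlap count for VLSM testing
#'
#' The smallest integer at least `fraction` of the cohort: voxels lesioned
#' in fewer participants are not tested, the usual 5% power threshold in the
#' VLSM literature.
#'
#' @param n_participants cohort size.
#' @param fraction overlap fraction in (0, 1) (default 0.05).
#' @return integer participant count.
#' @export
min_overlap_count <- function(n_participants, fraction = 0.05) {
  stopifnot_scalar_count(n_participants, "n_participants")
  stopifnot_fraction(fraction, "fraction")
  as.integer(ceiling(fraction * n_participants))
}

masks_to_matrix <- function(masks) {
  dims <- lapply(masks, function(m) dim(m$data))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stop("all masks must share one voxel grid", call. = FALSE)
  }
  ij <- lapply(seq_along(masks), function(i) {
    v <- which(masks[[i]]$data == 1L)
    cbind(i = rep(i, length(v)), j = v)
  })
  ij <- do.call(rbind, ij)
  Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = 1,
                       dims = c(length(masks), prod(dims[[1]])))
}

#' Voxel-wise lesion-symptom map
#'
#' At every voxel meeting the minimum-overlap criterion, participants are
#' split into those with and without a lesion at that voxel and their
#' behavioural scores compared. The default statistic is the pooled-variance
#' two-sample t, mapped to a z-score through the normal quantile of the t
#' cumulative probability; `test = "ranksum"` uses the normal-approximation
#' rank-sum statistic instead. The sign is positive when the lesioned group
#' scores higher (worse). Voxels where either group has fewer than 2
#' members are left untested even if the overlap criterion passes.
#'
#' @param masks list of [lesion_mask()] on a common grid.
#' @param scores numeric behavioural score per participant (same order).
#' @param fraction minimum overlap fraction (default 0.05).
#' @param test `"t"` (pooled-variance t, default) or `"ranksum"`.
#' @return object of class `vlsm_map`: `z` (3D array, NA where untested),
#'   `tested` (logical array), `overlap` (count array), `min_overlap`,
#'   `voxel_size`, `n`.
#' @export
vlsm_zmap <- function(masks, scores, fraction = 0.05, test = c("t", "ranksum")) {
  test <- match.arg(test)
  n <- length(masks)
  if (length(scores) != n) stop("masks and scores lengths differ", call. = FALSE)
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  dims <- dim(masks[[1]]$data)
  M <- masks_to_matrix(masks)
  n1 <- as.vector(Matrix::colSums(M))           # lesioned count per voxel
  n0 <- n - n1
  mo <- min_overlap_count(n, fraction)
  tested <- n1 >= mo & n1 >= 2 & n0 >= 2
  z <- rep(NA_real_, length(n1))
  idx <- which(tested)
  if (length(idx)) {
    Mi <- M[, idx, drop = FALSE]
    if (test == "t") {
      s1 <- as.vector(Matrix::crossprod(Mi, scores))
      s1sq <- as.vector(Matrix::crossprod(Mi, scores^2))
      k1 <- n1[idx]; k0 <- n0[idx]
      m1 <- s1 / k1
      m0 <- (sum(scores) - s1) / k0
      ss1 <- s1sq - k1 * m1^2
      ss0 <- (sum(scores^2) - s1sq) - k0 * m0^2
      df <- k1 + k0 - 2
      sp2 <- (ss1 + ss0) / df
      tt <- (m1 - m0) / sqrt(sp2 * (1 / k1 + 1 / k0))
      tt[!is.finite(tt)] <- 0          # zero pooled variance, equal means
      zz <- qnorm(pt(tt, df))
      zz[sp2 <= 0 & m1 == m0] <- 0
    } else {
      r <- rank(scores)
      sr1 <- as.vector(Matrix::crossprod(Mi, r))
      k1 <- n1[idx]; k0 <- n0[idx]
      u <- sr1 - k1 * (k1 + 1) / 2
      mu <- k1 * k0 / 2
      ties <- table(scores)
      tie_term <- sum(ties^3 - ties) / (n * (n - 1))
      sig <- sqrt(k1 * k0 / 12 * (n + 1 - tie_term))
      zz <- ifelse(sig > 0, (u - mu) / sig, 0)
    }
    # guard against +/-Inf from saturated pt()
    zz <- pmin(pmax(zz, -8.21), 8.21)
    z[idx] <- zz
  }
  structure(list(z = array(z, dim = dims),
                 tested = array(tested, dim = dims),
                 overlap = array(as.integer(n1), dim = dims),
                 min_overlap = mo, n = n,
                 voxel_size = masks[[1]]$voxel_size,
                 test = test),
            class = "vlsm_map")
}

#' @export
print.vlsm_map <- function(x, ...) {
  cat(sprintf("<vlsm_map> %s grid, %d/%d voxels tested (overlap >= %d of %d)\n",
              paste(dim(x$z), collapse = "x"), sum(x$tested), length(x$tested),
              x$min_overlap, x$n))
  invisible(x)
}

#' Mean VLSM z over a participant's lesion
#'
#' The mean of the z-map over the participant's lesioned voxels that were
#' tested: a scalar summary of how strongly that lesion's location is
#' associated with the behavioural score. A lesion with no tested voxels
#' yields 0 with attribute `"no_tested_voxels" = TRUE`.
#'
#' @param mask a [lesion_mask()] on the same grid as `map`.
#' @param map a [vlsm_zmap()].
#' @return scalar mean z.
#' @export
vlsm_mean_z <- function(mask, map) {
  stopifnot(inherits(mask, "lesion_mask"), inherits(map, "vlsm_map"))
  if (!identical(dim(mask$data), dim(map$z))) {
    stop("mask and map voxel grids differ", call. = FALSE)
  }
  sel <- mask$data == 1L & map$tested
  if (!any(sel)) {
    out <- 0
    attr(out, "no_tested_voxels") <- TRUE
    return(out)
  }
  mean(map$z[sel])
}

#' VLSM mean Z for every participant of a cohort
#'
#' @param masks list of [lesion_mask()].
#' @param map a [vlsm_zmap()] computed on a compatible grid.
#' @return numeric vector, one value per mask.
#' @export
vlsm_mean_z_all <- function(masks, map) {
  vapply(masks, vlsm_mean_z, numeric(1), map = map)
}

#' Write / read lesion masks as NIfTI
#'
#' Masks are written as gzipped NIfTI volumes with the voxel size recorded
#' in the header.
#'
#' @param mask a [lesion_mask()] (or, for the z-map writer, a `vlsm_map`).
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_lesion_mask <- function(mask, path) {
  stopifnot(inherits(mask, "lesion_mask"))
  img <- RNifti::asNifti(mask$data)
  RNifti::pixdim(img) <- mask$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_lesion_mask
#' @param space space tag to attach on read.
#' @export
read_lesion_mask <- function(path, space = "unspecified") {
  img <- RNifti::readNifti(path)
  lesion_mask(array(as.integer(img > 0.5), dim = dim(img)),
              voxel_size = RNifti::pixdim(img)[1:3], space = space)
}

#' @rdname write_lesion_mask
#' @param map a `vlsm_map`.
#' @export
write_vlsm_map <- function(map, path) {
  stopifnot(inherits(map, "vlsm_map"))
  z <- map$z
  z[!map$tested] <- 0
  img <- RNifti::asNifti(z)
  RNifti::pixdim(img) <- map$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}
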
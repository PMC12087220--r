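# Spatial co-occurrence of toxins across the gland section and
# anterior-posterior localization testing on ion-image stacks.

#' Pairwise spatial correlation (co-occurrence) of toxin images
#'
#' Pearson correlation between each toxin pair's intensities over masked
#' pixels, optionally after per-pixel total-ion-current normalization across
#' the stack. A cosine-similarity alternative is available since the exact
#' co-occurrence statistic of commercial MSI software is not public.
#'
#' @param stack an [ion_image_stack()].
#' @param normalize "none" (default) or "tic".
#' @param method "pearson" (default) or "cosine".
#' @return symmetric `pair_matrix` with unit diagonal; constant images give
#'   missing entries with a warning.
#' @export
spatial_correlation <- function(stack, normalize = c("none", "tic"),
                                method = c("pearson", "cosine")) {
  normalize <- match.arg(normalize)
  method <- match.arg(method)
  stopifnot(inherits(stack, "ion_image_stack"))
  if (length(stack$images) < 2)
    stop("need at least 2 toxin images", call. = FALSE)
  if (!any(stack$mask)) stop("mask is empty", call. = FALSE)
  m <- vapply(stack$images, function(img) img[stack$mask],
              numeric(sum(stack$mask)))
  if (normalize == "tic") {
    tic <- rowSums(m)
    m <- m / ifelse(tic > 0, tic, 1)
  }
  if (method == "pearson") {
    const <- apply(m, 2, function(v) sd(v) == 0)
    r <- suppressWarnings(cor(m))
    if (any(const)) {
      warning("constant images yield undefined correlations: ",
              paste(colnames(m)[const], collapse = ", "), call. = FALSE)
      r[const, ] <- NA_real_
      r[, const] <- NA_real_
    }
    diag(r) <- ifelse(const, NA_real_, 1)
  } else {
    nrm <- sqrt(colSums(m^2))
    r <- crossprod(m) / outer(nrm, nrm)
    bad <- nrm == 0
    r[bad, ] <- NA_real_
    r[, bad] <- NA_real_
    diag(r) <- ifelse(bad, NA_real_, 1)
  }
  new_pair_matrix(r, paste0("spatial_", method), "similarity")
}

axis_coordinates <- function(stack) {
  dims <- dim(stack$mask)
  if (stack$axis$dim == "col") {
    x <- matrix(rep((seq_len(dims[2]) - 1) / max(dims[2] - 1, 1),
                    each = dims[1]), dims[1], dims[2])
  } else {
    x <- matrix(rep((seq_len(dims[1]) - 1) / max(dims[1] - 1, 1), dims[2]),
                dims[1], dims[2])
  }
  if (isTRUE(stack$axis$reverse)) x <- 1 - x
  x
}

#' Intensity-weighted anterior-posterior centroid per toxin
#'
#' The centroid is the intensity-weighted mean of the normalized axis
#' coordinate (anterior = 0, posterior = 1) over masked pixels.
#'
#' @param stack an [ion_image_stack()].
#' @return named numeric vector of centroids in [0, 1]; all-zero images
#'   yield missing values with a warning.
#' @export
axis_localization <- function(stack) {
  stopifnot(inherits(stack, "ion_image_stack"))
  x <- axis_coordinates(stack)[stack$mask]
  out <- vapply(stack$images, function(img) {
    w <- img[stack$mask]
    if (sum(w) == 0) return(NA_real_)
    sum(w * x) / sum(w)
  }, 0)
  if (anyNA(out))
    warning("all-zero images have no centroid: ",
            paste(names(out)[is.na(out)], collapse = ", "), call. = FALSE)
  out
}

#' One-way ANOVA of axis centroids by toxin group
#'
#' Tests whether functional groups (e.g. neurotoxin-like vs cytotoxin-like)
#' occupy different positions along the gland axis.
#'
#' @param centroids named vector from [axis_localization()].
#' @param groups named group labels matching the centroids.
#' @return list with `f`, `p`, `group_means`, `centroids`, `groups`.
#' @export
group_location_test <- function(centroids, groups) {
  groups <- groups[names(centroids)]
  ok <- !is.na(centroids)
  centroids <- centroids[ok]; groups <- factor(groups[ok])
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) == 0))
    stop("a group has zero members", call. = FALSE)
  fit <- aov(centroids ~ groups)
  tab <- anova(fit)
  list(f = tab$`F value`[1], p = tab$`Pr(>F)`[1],
       group_means = tapply(centroids, groups, mean),
       centroids = centroids, groups = groups)
}
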
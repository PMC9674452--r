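# Predictor and response distance matrices: great-circle geographic,
# PCA-reduced climatic, and Mahalanobis quantitative-trait distances.

#' Great-circle distances between population sites
#'
#' Haversine distances (Earth radius 6371.0 km) between site coordinates.
#'
#' @param sites data.frame with \code{population_id}, \code{latitude},
#'   \code{longitude} in decimal degrees.
#' @return Symmetric matrix of distances in km, labeled by population.
#' @export
geographic_distances <- function(sites) {
  need <- c("population_id", "latitude", "longitude")
  stopifnot(all(need %in% names(sites)))
  if (any(abs(sites$latitude) > 90) || any(abs(sites$longitude) > 180))
    stop("coordinates out of range")
  xy <- cbind(sites$longitude, sites$latitude)
  P <- nrow(xy)
  d <- matrix(0, P, P, dimnames = list(sites$population_id,
                                       sites$population_id))
  for (i in seq_len(P - 1)) {
    d[i, (i + 1):P] <- geosphere::distHaversine(
      xy[i, , drop = FALSE], xy[(i + 1):P, , drop = FALSE], r = 6371000
    ) / 1000
  }
  d <- d + t(d)
  check_dist_matrix(d, "geographic distance matrix")
}

#' Principal component analysis of site climate
#'
#' PCA on standardized (zero mean, unit variance) bioclimatic variables.
#' Constant variables are dropped with a warning.  Component signs are fixed
#' by forcing the largest-magnitude loading of each component positive.
#'
#' @param climate data.frame with \code{population_id} and numeric climate
#'   columns.
#' @param k number of components to retain.
#' @return List of class \code{climate_pca}: \code{scores} (populations x k),
#'   \code{explained} (\% variance per component, all components),
#'   \code{correlations} (variable--component correlations for the retained
#'   components), \code{k}.
#' @export
climate_pca <- function(climate, k = 2) {
  stopifnot("population_id" %in% names(climate))
  vars <- setdiff(names(climate), "population_id")
  x <- as.matrix(climate[vars])
  if (anyNA(x)) stop("climate table has missing cells")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant climate variable(s): ",
            paste(vars[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (nrow(x) < k + 1) stop("need at least k + 1 populations")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  # sign convention: largest-|loading| entry positive
  for (j in seq_len(ncol(pc$rotation))) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  expl <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- climate$population_id
  corr <- stats::cor(x, scores)
  structure(
    list(scores = scores, explained = expl, correlations = corr, k = k),
    class = "climate_pca"
  )
}

#' Climatic distances on retained principal components
#'
#' @param pca a \code{climate_pca} object (or a score matrix).
#' @return Symmetric Euclidean distance matrix on the retained components.
#' @export
climatic_distances <- function(pca) {
  scores <- if (inherits(pca, "climate_pca")) pca$scores else as.matrix(pca)
  d <- as.matrix(stats::dist(scores))
  dimnames(d) <- list(rownames(scores), rownames(scores))
  check_dist_matrix(d, "climatic distance matrix")
}

#' Mahalanobis distances between population trait means
#'
#' Traits are averaged over seed families; population mean vectors are
#' compared under the pooled within-population covariance of family means
#' (df-weighted), so the distance is invariant to invertible affine
#' re-scaling of the traits.
#'
#' @param traits trait table with \code{population_id}, \code{family_id} and
#'   trait columns.
#' @param trait_transforms named character vector mapping trait columns to
#'   \code{"none"}/\code{"sqrt"}; transformed scales are used throughout.
#' @param squared return squared distances instead of distances.
#' @return Symmetric matrix of Mahalanobis distances between populations.
#' @export
mahalanobis_distances <- function(traits, trait_transforms, squared = FALSE) {
  trait_names <- names(trait_transforms)
  stopifnot(length(trait_names) >= 2)
  validate_traits(traits, trait_names[1])
  tx <- traits
  for (trait in trait_names)
    tx[[trait]] <- apply_transform(traits[[trait]], trait_transforms[[trait]])
  fam_means <- stats::aggregate(
    tx[trait_names],
    by = list(population_id = tx$population_id, family_id = tx$family_id),
    FUN = mean, na.rm = TRUE
  )
  pops <- unique(fam_means$population_id)
  P <- length(pops)
  pop_means <- t(vapply(pops, function(p) {
    colMeans(fam_means[fam_means$population_id == p, trait_names,
                       drop = FALSE])
  }, numeric(length(trait_names))))
  rownames(pop_means) <- pops
  # pooled within-population covariance of family means
  S <- matrix(0, length(trait_names), length(trait_names))
  df_total <- 0
  for (p in pops) {
    fm <- as.matrix(fam_means[fam_means$population_id == p, trait_names,
                              drop = FALSE])
    if (nrow(fm) < 2) next
    S <- S + stats::cov(fm) * (nrow(fm) - 1)
    df_total <- df_total + nrow(fm) - 1
  }
  if (df_total == 0) stop("no population with >= 2 families")
  S <- S / df_total
  cn <- kappa(S, exact = TRUE)
  S_inv <- tryCatch(solve(S), error = function(e) {
    stop(sprintf(paste0("pooled covariance is singular (condition number ",
                        "%.3g); consider removing a trait"), cn))
  })
  d <- matrix(0, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P - 1)) {
    for (j in seq(i + 1, P)) {
      diff <- pop_means[i, ] - pop_means[j, ]
      d2 <- drop(t(diff) %*% S_inv %*% diff)
      d[i, j] <- d[j, i] <- if (squared) d2 else sqrt(d2)
    }
  }
  attr(d, "condition_number") <- cn
  check_dist_matrix(d, "Mahalanobis distance matrix")
}

#' Write a distance matrix as square CSV or PHYLIP-style text
#'
#' @param d labeled symmetric matrix.
#' @param path output path.
#' @param format \code{"csv"} or \code{"phylip"}.
#' @return \code{path}, invisibly.
#' @export
write_dist_matrix <- function(d, path, format = c("csv", "phylip")) {
  format <- match.arg(format)
  check_dist_matrix(d, nonneg = FALSE)
  if (format == "csv") {
    utils::write.csv(as.data.frame(d), path)
  } else {
    lines <- c(
      sprintf("%5d", nrow(d)),
      vapply(seq_len(nrow(d)), function(i) {
        paste0(formatC(rownames(d)[i], width = -10),
               paste(sprintf("%.6f", d[i, ]), collapse = "  "))
      }, character(1))
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Long-format pair table from distance matrices
#'
#' One row per unordered population pair, with one column per named matrix;
#' the standard input for pairwise distance regressions.
#'
#' @param ... named labeled symmetric matrices over the same populations.
#' @return data.frame with \code{pop1}, \code{pop2} and one value column per
#'   matrix.
#' @export
pair_table <- function(...) {
  mats <- list(...)
  stopifnot(length(mats) >= 1, !is.null(names(mats)), all(names(mats) != ""))
  labs <- rownames(mats[[1]])
  out <- lower_pairs(mats[[1]])
  names(out)[3] <- names(mats)[1]
  for (k in seq_along(mats)[-1]) {
    m <- mats[[k]]
    if (!identical(rownames(m), labs))
      m <- m[labs, labs]
    out[[names(mats)[k]]] <- lower_pairs(m)$value
  }
  out
}
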
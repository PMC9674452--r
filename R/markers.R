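# Genotyping-error estimation, clone calling and assembly of the neutral-locus
# analysis matrix for dominant marker data.

#' Estimate the genotyping error rate from replicated scores
#'
#' Dominant-marker scoring error is estimated by re-scoring a subset of
#' sample x marker combinations and counting disagreements.  Only score pairs
#' non-missing in both runs are comparable.
#'
#' @param original,replicate equal-length vectors (or matrices) of 0/1/NA
#'   scores over identical loci; alternatively a list of such pairs.
#' @return A list of class \code{error_rate}: \code{e} (mismatch proportion),
#'   \code{n_compared}, \code{n_mismatch}.
#' @export
estimate_error_rate <- function(original, replicate) {
  if (is.list(original) && missing(replicate)) {
    pairs <- original
  } else {
    pairs <- list(list(original, replicate))
  }
  n_comp <- 0L
  n_mis <- 0L
  for (p in pairs) {
    a <- as.integer(unlist(p[[1]]))
    b <- as.integer(unlist(p[[2]]))
    if (length(a) != length(b))
      stop("replicate score vectors must have equal length")
    ok <- !is.na(a) & !is.na(b)
    n_comp <- n_comp + sum(ok)
    n_mis <- n_mis + sum(a[ok] != b[ok])
  }
  if (n_comp == 0L)
    stop("no comparable (non-missing in both runs) scores")
  structure(
    list(e = n_mis / n_comp, n_compared = n_comp, n_mismatch = n_mis),
    class = "error_rate"
  )
}

#' Fraction of the dataset covered by replicate scoring
#'
#' @param n_replicated number of repeated banding scores.
#' @param n_individuals,n_loci dimensions of the full score matrix.
#' @return Proportion of all scores that were re-scored.
#' @export
replicate_coverage <- function(n_replicated, n_individuals, n_loci) {
  stopifnot(n_replicated >= 0, n_individuals >= 1, n_loci >= 1)
  n_replicated / (n_individuals * n_loci)
}

#' Clone-calling threshold from the error rate
#'
#' Two plants whose band phenotypes differ at no more loci than expected from
#' scoring error alone are treated as putative clones.  The expected number of
#' discordant loci between two error-affected copies of the same genotype is
#' approximately \code{e * n_loci}; the integer threshold rounds half up.
#'
#' @param e an \code{error_rate} object or a bare proportion.
#' @param n_loci number of scored loci.
#' @return List with \code{raw} (e * n_loci) and \code{threshold} (integer).
#' @export
clone_threshold <- function(e, n_loci) {
  if (inherits(e, "error_rate")) e <- e$e
  stopifnot(n_loci >= 1, e >= 0, e <= 1)
  raw <- e * n_loci
  list(raw = raw, threshold = as.integer(round_half_up(raw)))
}

#' Detect putative clones by multilocus genotype matching
#'
#' Counts pairwise Hamming mismatches over loci scored in both individuals and
#' joins any pair with mismatch count at or below the threshold.  Clone groups
#' are the connected components of the resulting match graph, so chained
#' matches (A~B, B~C) fall into one group even if A and C differ by more than
#' the threshold.
#'
#' @param m a [marker_matrix].
#' @param threshold maximum number of mismatching loci for two individuals to
#'   be called the same genotype.
#' @return A list of class \code{clone_call}: \code{groups} (list of id
#'   vectors, a partition of all individuals), \code{threshold},
#'   \code{pair_distances_m} (transect distances within matched pairs, when
#'   positions are available), and \code{n_groups}.
#' @export
detect_clones <- function(m, threshold) {
  stopifnot(inherits(m, "marker_matrix"), threshold >= 0)
  ids <- rownames(m$scores)
  n <- length(ids)
  x <- m$scores
  # pairwise mismatch counts over mutually scored loci
  pres <- !is.na(x)
  x0 <- x; x0[!pres] <- 0L
  both <- tcrossprod(pres * 1L)                     # comparable loci per pair
  agree11 <- tcrossprod(x0)                         # both bands present
  agree00 <- tcrossprod((1L - x0) * (pres * 1L))    # both bands absent
  mismatch <- both - agree11 - agree00
  hit <- mismatch <= threshold & both > 0
  diag(hit) <- FALSE
  edges <- which(hit & upper.tri(hit), arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[edges[, 1]], to = ids[edges[, 2]]),
    directed = FALSE,
    vertices = data.frame(name = ids)
  )
  comp <- igraph::components(g)
  groups <- split(ids, comp$membership)
  names(groups) <- NULL
  pair_d <- numeric(0)
  if (nrow(edges) > 0 && any(!is.na(m$position))) {
    same_pop <- m$population[edges[, 1]] == m$population[edges[, 2]]
    pair_d <- abs(m$position[edges[, 1]] - m$position[edges[, 2]])[same_pop]
    pair_d <- pair_d[!is.na(pair_d)]
  }
  structure(
    list(groups = groups, threshold = threshold,
         pair_distances_m = pair_d, n_groups = length(groups)),
    class = "clone_call"
  )
}

#' Keep one randomly chosen member of each clone group
#'
#' @param m a [marker_matrix].
#' @param call a \code{clone_call} from [detect_clones] on the same matrix.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return A [marker_matrix] with one individual per clone group, in the
#'   original row order.  The seed and the retained ids are attached as
#'   attributes \code{seed} and \code{kept_ids}.
#' @export
deduplicate <- function(m, call, seed) {
  stopifnot(inherits(m, "marker_matrix"), inherits(call, "clone_call"))
  ids <- rownames(m$scores)
  if (!setequal(unlist(call$groups), ids))
    stop("clone call does not partition the individuals of this matrix")
  rng <- local({
    set.seed(seed)
    function(k) sample.int(k, 1L)
  })
  kept <- vapply(call$groups, function(g) g[rng(length(g))], character(1))
  keep_idx <- sort(match(kept, ids))
  out <- subset_individuals(m, keep_idx)
  attr(out, "seed") <- seed
  attr(out, "kept_ids") <- ids[keep_idx]
  out
}

#' Drop loci by name (e.g. loci flagged as non-neutral)
#'
#' @param m a [marker_matrix].
#' @param exclude character vector of locus names to remove.
#' @return A [marker_matrix] without the listed loci, order preserved.
#' @export
drop_loci <- function(m, exclude) {
  stopifnot(inherits(m, "marker_matrix"))
  if (length(exclude) == 0) return(m)
  unknown <- setdiff(exclude, colnames(m$scores))
  if (length(unknown) > 0)
    stop("unknown locus name(s): ", paste(unknown, collapse = ", "))
  keep <- setdiff(colnames(m$scores), exclude)
  if (length(keep) == 0) stop("cannot remove all loci")
  marker_matrix(m$scores[, keep, drop = FALSE], m$population, m$position)
}
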
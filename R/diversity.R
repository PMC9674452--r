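# Within-population diversity from dominant-marker allele frequencies.

#' Nei's gene diversity per population
#'
#' Expected heterozygosity averaged over marker loci, computed from the
#' estimated null-allele frequencies: H = mean over loci of 2 q (1 - q).
#' For biallelic loci H is at most 0.5.
#'
#' @param freqs an \code{allele_freqs} object from [estimate_allele_freqs],
#'   or a populations x loci matrix of allele frequencies.
#' @return Named numeric vector of per-population gene diversity.
#' @export
gene_diversity <- function(freqs) {
  q <- if (inherits(freqs, "allele_freqs")) freqs$q else as.matrix(freqs)
  rowMeans(2 * q * (1 - q), na.rm = TRUE)
}

#' Percentage of polymorphic loci at a frequency level
#'
#' A locus is polymorphic in a population when its estimated allele frequency
#' lies strictly between \code{level} and \code{1 - level} (the classical
#' "5\% level" uses \code{level = 0.05}).
#'
#' @param freqs an \code{allele_freqs} object or frequency matrix.
#' @param level polymorphism level in (0, 0.5).
#' @return Named numeric vector of per-population percentages in \[0, 100\].
#' @export
ppl <- function(freqs, level = 0.05) {
  stopifnot(level > 0, level < 0.5)
  q <- if (inherits(freqs, "allele_freqs")) freqs$q else as.matrix(freqs)
  100 * rowMeans(q > level & q < 1 - level, na.rm = TRUE)
}

#' Per-population diversity table
#'
#' @param freqs an \code{allele_freqs} object.
#' @param level polymorphism level passed to [ppl].
#' @return data.frame with population, n, PPL and H_eN plus a final
#'   \code{"mean"} row averaging over populations.
#' @export
diversity_table <- function(freqs, level = 0.05) {
  stopifnot(inherits(freqs, "allele_freqs"))
  h <- gene_diversity(freqs)
  p <- ppl(freqs, level)
  df <- data.frame(
    population = rownames(freqs$q),
    n = as.integer(freqs$n),
    PPL = p,
    H_eN = h,
    stringsAsFactors = FALSE
  )
  rbind(df, data.frame(population = "mean", n = NA_integer_,
                       PPL = mean(p), H_eN = mean(h)))
}
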
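#' Marker matrix of dominant band scores
#'
#' Container for a binary individual x locus band presence/absence matrix
#' (RAPD/AFLP-style dominant markers) with population labels and optional
#' within-transect positions.  Band scores are phenotypes: 1 = band present,
#' 0 = band absent, \code{NA} = not scored.
#'
#' @param scores integer/numeric matrix of 0/1/\code{NA}, individuals in rows,
#'   loci in columns.  Row names are individual ids, column names locus names;
#'   defaults are generated when absent.
#' @param population character vector of population labels, one per row.
#' @param position optional numeric vector of transect positions in metres.
#'
#' @return An object of class \code{marker_matrix}: a list with elements
#'   \code{scores}, \code{population} and \code{position}.
#' @export
marker_matrix <- function(scores, population, position = NULL) {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores)))
    rownames(scores) <- paste0("ind", seq_len(nrow(scores)))
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("L", seq_len(ncol(scores)))
  storage.mode(scores) <- "integer"
  if (nrow(scores) == 0L || ncol(scores) == 0L)
    stop("marker matrix must have at least one individual and one locus")
  bad <- !(scores %in% c(0L, 1L, NA_integer_))
  if (any(bad))
    stop("scores must be 0, 1 or NA; offending values: ",
         paste(utils::head(unique(scores[bad]), 5), collapse = ", "))
  if (anyDuplicated(rownames(scores)))
    stop("duplicate individual ids")
  population <- as.character(population)
  if (length(population) != nrow(scores))
    stop("population labels must match the number of individuals")
  if (any(is.na(population) | population == ""))
    stop("population labels must be nonempty")
  if (is.null(position)) {
    position <- rep(NA_real_, nrow(scores))
  } else {
    position <- as.numeric(position)
    if (length(position) != nrow(scores))
      stop("transect positions must match the number of individuals")
  }
  all_missing <- colSums(!is.na(scores)) == 0L
  if (any(all_missing))
    stop("loci with no scored individuals: ",
         paste(colnames(scores)[all_missing], collapse = ", "))
  structure(
    list(scores = scores, population = population, position = position),
    class = "marker_matrix"
  )
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d individuals x %d loci, %d populations\n",
              nrow(x$scores), ncol(x$scores), length(unique(x$population))))
  miss <- mean(is.na(x$scores))
  cat(sprintf("  missing scores: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.marker_matrix <- function(x) dim(x$scores)

#' Read a marker matrix from file
#'
#' Two dialects are supported.  \code{"csv"} expects columns
#' \code{individual_id}, \code{population_id}, optionally
#' \code{transect_position}, then one 0/1/NA column per locus.
#' \code{"genalex"} expects the GenAlEx export layout: a first header row
#' \code{n_loci, n_samples, n_pops, size_1, ..., size_P}, a second row with a
#' dataset title and the population names, a third row with
#' \code{sample, pop, <locus names>}, then one data row per individual.
#'
#' @param path file path.
#' @param dialect \code{"csv"} or \code{"genalex"}.
#' @return A [marker_matrix].
#' @export
read_marker_matrix <- function(path, dialect = c("csv", "genalex")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "csv") read_marker_csv(path) else read_marker_genalex(path)
}

read_marker_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("individual_id", "population_id")
  if (!all(need %in% names(raw)))
    stop("csv marker file must have columns individual_id and population_id")
  has_pos <- "transect_position" %in% names(raw)
  meta_cols <- c(need, if (has_pos) "transect_position")
  locus_cols <- setdiff(names(raw), meta_cols)
  if (length(locus_cols) == 0L) stop("no locus columns found")
  scores <- as.matrix(raw[locus_cols])
  bad_sym <- matrix(!(scores %in% c("0", "1", 0, 1, NA)), nrow(scores))
  if (any(bad_sym)) {
    i <- which(bad_sym, arr.ind = TRUE)[1, ]
    stop(sprintf("unknown score symbol '%s' at row %d, locus %s",
                 scores[bad_sym][1], i[1], locus_cols[i[2]]))
  }
  storage.mode(scores) <- "integer"
  rownames(scores) <- raw$individual_id
  marker_matrix(scores, raw$population_id,
                if (has_pos) raw$transect_position else NULL)
}

read_marker_genalex <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4L) stop("genalex file too short: ", path)
  split_row <- function(s) {
    out <- strsplit(s, ",", fixed = TRUE)[[1]]
    trimws(out)
  }
  hdr <- suppressWarnings(as.integer(split_row(lines[1])))
  if (length(hdr) < 3L || anyNA(hdr[1:3]))
    stop("genalex header row must start with n_loci, n_samples, n_pops")
  n_loci <- hdr[1]; n_samples <- hdr[2]; n_pops <- hdr[3]
  sizes <- hdr[3 + seq_len(n_pops)]
  if (anyNA(sizes) || sum(sizes) != n_samples)
    stop("genalex population sizes do not sum to the sample count")
  col_hdr <- split_row(lines[3])
  locus_names <- col_hdr[2 + seq_len(n_loci)]
  data_lines <- lines[3 + seq_len(n_samples)]
  rows <- lapply(seq_along(data_lines), function(i) {
    f <- split_row(data_lines[i])
    if (length(f) < 2 + n_loci)
      stop(sprintf("genalex row %d has %d fields, expected %d",
                   i, length(f), 2 + n_loci))
    f[seq_len(2 + n_loci)]
  })
  tab <- do.call(rbind, rows)
  scr <- tab[, 2 + seq_len(n_loci), drop = FALSE]
  scr[scr %in% c("", "-9", "NA")] <- NA
  bad <- !(scr %in% c("0", "1", NA))
  if (any(bad))
    stop("unknown score symbol in genalex body: ", scr[bad][1])
  scores <- matrix(as.integer(scr), nrow = n_samples,
                   dimnames = list(tab[, 1], locus_names))
  marker_matrix(scores, tab[, 2])
}

#' Write a marker matrix to file
#'
#' @param m a [marker_matrix].
#' @param path output path.
#' @param dialect \code{"csv"} or \code{"genalex"} (see [read_marker_matrix]).
#' @param title dataset title placed in the GenAlEx header.
#' @return \code{path}, invisibly.
#' @export
write_marker_matrix <- function(m, path, dialect = c("csv", "genalex"),
                                title = "fragpop export") {
  dialect <- match.arg(dialect)
  stopifnot(inherits(m, "marker_matrix"))
  if (dialect == "csv") {
    df <- data.frame(
      individual_id = rownames(m$scores),
      population_id = m$population,
      transect_position = m$position,
      m$scores,
      check.names = FALSE,
      stringsAsFactors = FALSE
    )
    utils::write.csv(df, path, row.names = FALSE, na = "")
  } else {
    # keep individuals grouped by population, preserving first-seen order
    ord <- order(match(m$population, unique(m$population)))
    pops <- m$population[ord]
    sizes <- table(factor(pops, levels = unique(pops)))
    n_loci <- ncol(m$scores)
    l1 <- paste(c(n_loci, nrow(m$scores), length(sizes), as.integer(sizes)),
                collapse = ",")
    l2 <- paste(c(title, "", names(sizes)), collapse = ",")
    l3 <- paste(c("sample", "pop", colnames(m$scores)), collapse = ",")
    body <- vapply(ord, function(i) {
      paste(c(rownames(m$scores)[i], m$population[i],
              ifelse(is.na(m$scores[i, ]), "-9", m$scores[i, ])),
            collapse = ",")
    }, character(1))
    writeLines(c(l1, l2, l3, body), path)
  }
  invisible(path)
}

#' Subset a marker matrix by individuals
#'
#' @param m a [marker_matrix].
#' @param keep individual ids or logical/integer index over rows.
#' @return A [marker_matrix] with the selected individuals.
#' @export
subset_individuals <- function(m, keep) {
  stopifnot(inherits(m, "marker_matrix"))
  if (is.character(keep)) keep <- match(keep, rownames(m$scores))
  if (anyNA(keep)) stop("unknown individual id in subset")
  marker_matrix(m$scores[keep, , drop = FALSE],
                m$population[keep], m$position[keep])
}
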
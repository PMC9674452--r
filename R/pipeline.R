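# End-to-end orchestration: markers -> popgen; traits -> quantgen;
# sites/climate -> distances; inference; consolidated report.

#' Default run configuration
#'
#' Defaults match the classic analysis settings: F_IS = 0.643, selfing
#' fraction 0.55, 1000 permutations, polymorphism at the 5\% level.
#'
#' @return Named list of configuration defaults.
#' @export
default_config <- function() {
  list(
    markers = NULL, replicates = NULL, traits = NULL,
    sites = NULL, climate = NULL,
    f_is = 0.643,
    selfing_fraction = 0.55,
    n_perm = 1000,
    seed = 17,
    ppl_level = 0.05,
    exclude_loci = character(0),
    trait_transforms = c(diameter = "none", leaf_width = "none",
                         flowers = "sqrt"),
    out_dir = NULL
  )
}

#' Read a run configuration from YAML
#'
#' Unset keys fall back to [default_config]; file paths are resolved
#' relative to the YAML file's directory.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  if (!is.null(user$trait_transforms))
    cfg$trait_transforms <- unlist(user$trait_transforms)
  base <- dirname(normalizePath(path))
  for (key in c("markers", "replicates", "traits", "sites", "climate")) {
    if (is.character(cfg[[key]]) && !file.exists(cfg[[key]]))
      cfg[[key]] <- file.path(base, cfg[[key]])
  }
  cfg
}

read_table_input <- function(x, what) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) return(x)
  if (is.character(x)) {
    if (!file.exists(x)) stop(what, " file not found: ", x)
    return(utils::read.csv(x, stringsAsFactors = FALSE))
  }
  x
}

#' Run the complete analysis pipeline
#'
#' Executes every stage in dependency order: clone screening and locus
#' exclusion on the marker matrix; allele frequencies, diversity, F_ST (with
#' permutation test), pairwise F_ST/distinctness and AMOVA; nested variance
#' components, heritability, evolvability and Q_ST with jackknife CIs;
#' geographic, climatic and Mahalanobis distance matrices; and the inference
#' layer (isolation-by-distance tests, sequential permutation regression of
#' quantitative distance on molecular, climatic and geographic distances,
#' distinctness--diversity and diversity--size correlations, evolvability
#' t-tests, Q_ST--F_ST comparison).  When \code{out_dir} is set, per-stage
#' CSVs and a JSON summary are written.
#'
#' @param config configuration list (see [default_config]) or a YAML path.
#'   Inputs \code{markers}, \code{traits}, \code{sites}, \code{climate} may
#'   be file paths or in-memory objects; \code{markers} may also be a
#'   [marker_matrix].  \code{replicates} is an optional list of score-vector
#'   pairs for error-rate estimation.
#' @return List of class \code{fragpop_report} with elements per stage.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- utils::modifyList(default_config(), config)
  out <- list(config = cfg[setdiff(names(cfg),
                                   c("markers", "replicates", "traits",
                                     "sites", "climate"))])
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## -- markers -------------------------------------------------------------
  m <- stage("markers", {
    mm <- cfg$markers
    if (is.character(mm)) mm <- read_marker_matrix(mm, "csv")
    if (!inherits(mm, "marker_matrix"))
      stop("no marker input provided")
    mm
  })
  out$markers <- stage("clone_screen", {
    res <- list(n_input = nrow(m$scores))
    if (!is.null(cfg$replicates)) {
      er <- estimate_error_rate(cfg$replicates)
      res$error_rate <- er
      thr <- clone_threshold(er, ncol(m$scores))
    } else if (!is.null(cfg$error_rate)) {
      res$error_rate <- list(e = cfg$error_rate)
      thr <- clone_threshold(cfg$error_rate, ncol(m$scores))
    } else {
      thr <- list(raw = 0, threshold = 0L)
    }
    res$threshold <- thr
    call <- detect_clones(m, thr$threshold)
    res$clone_groups <- Filter(function(g) length(g) > 1, call$groups)
    res$pair_distances_m <- call$pair_distances_m
    m2 <- deduplicate(m, call, cfg$seed)
    m2 <- drop_loci(m2, cfg$exclude_loci)
    res$n_kept <- nrow(m2$scores)
    res$n_loci <- ncol(m2$scores)
    res$clean <- m2
    res
  })
  mclean <- out$markers$clean

  ## -- dominant-marker popgen ----------------------------------------------
  out$popgen <- stage("popgen", {
    freqs <- estimate_allele_freqs(mclean, cfg$f_is)
    div <- diversity_table(freqs, cfg$ppl_level)
    fst_t <- fst_permutation_test(mclean, cfg$f_is, cfg$n_perm, cfg$seed)
    pw <- pairwise_fst(freqs)
    list(freqs = freqs, diversity = div,
         fst = global_fst(freqs), fst_test = fst_t,
         pairwise_fst = pw, distinctness = distinctness(pw),
         amova = amova(mclean, min(cfg$n_perm, 999), cfg$seed))
  })

  ## -- quantgen --------------------------------------------------------------
  traits <- read_table_input(cfg$traits, "traits")
  if (!is.null(traits)) {
    out$quantgen <- stage("quantgen", {
      quantgen_summary(traits, cfg$trait_transforms, cfg$selfing_fraction)
    })
  }

  ## -- distances -------------------------------------------------------------
  sites <- read_table_input(cfg$sites, "sites")
  climate <- read_table_input(cfg$climate, "climate")
  if (!is.null(sites)) {
    out$distances <- stage("distances", {
      d <- list(geographic = geographic_distances(sites))
      if (!is.null(climate)) {
        d$pca <- climate_pca(climate)
        d$climatic <- climatic_distances(d$pca)
      }
      if (!is.null(traits))
        d$quantitative <- mahalanobis_distances(traits, cfg$trait_transforms)
      d
    })
  }

  ## -- inference -------------------------------------------------------------
  if (!is.null(sites) && !is.null(traits)) {
    out$inference <- stage("inference", {
      inf <- list()
      pops <- rownames(out$popgen$pairwise_fst)
      dgeo <- out$distances$geographic[pops, pops]
      inf$ibd_molecular <- ibd_test(out$popgen$pairwise_fst, dgeo,
                                    cfg$n_perm, cfg$seed)
      dq <- out$distances$quantitative[pops, pops]
      inf$ibd_quantitative <- ibd_test(dq, dgeo, cfg$n_perm, cfg$seed)
      if (!is.null(out$distances$climatic)) {
        dc <- out$distances$climatic[pops, pops]
        inf$sequential <- sequential_perm_regression(
          dq,
          list(molecular = out$popgen$pairwise_fst,
               climatic = dc, geographic = dgeo),
          cfg$n_perm, cfg$seed
        )
      }
      hen <- gene_diversity(out$popgen$freqs)
      inf$distinctness_vs_diversity <- correlate(
        out$popgen$distinctness[pops], hen[pops])
      sz <- sites$census_size[match(pops, sites$population_id)]
      if (!anyNA(sz)) {
        inf$diversity_vs_size <- correlate(hen[pops], sz)
        inf$diversity_vs_log_size <- correlate(hen[pops], log10(sz))
      }
      cvs <- lapply(out$quantgen$per_population, function(df) df$cv_genetic)
      inf$evolvability_t <- lapply(cvs, one_sample_t)
      inf$qst_fst <- compare_qst_fst(out$quantgen$global,
                                     out$popgen$fst_test)
      inf
    })
  }

  class(out) <- "fragpop_report"
  if (!is.null(cfg$out_dir)) write_report(out, cfg$out_dir)
  invisible(out)
}

#' Write a pipeline report to disk
#'
#' Per-stage CSVs (diversity table, pairwise F_ST, AMOVA table, quantitative
#' genetics global and per-population tables, distance matrices, sequential
#' regression table) plus a machine-readable \code{summary.json}.
#'
#' @param report a \code{fragpop_report} from [run_all].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  utils::write.csv(report$popgen$diversity, p("diversity.csv"),
                   row.names = FALSE)
  write_dist_matrix(report$popgen$pairwise_fst, p("pairwise_fst.csv"))
  write_dist_matrix(report$popgen$pairwise_fst, p("pairwise_fst.phy"),
                    "phylip")
  utils::write.csv(report$popgen$amova$table, p("amova.csv"),
                   row.names = FALSE)
  if (!is.null(report$quantgen)) {
    utils::write.csv(report$quantgen$global, p("quantgen_global.csv"),
                     row.names = FALSE)
    for (trait in names(report$quantgen$per_population))
      utils::write.csv(report$quantgen$per_population[[trait]],
                       p(sprintf("quantgen_%s.csv", trait)),
                       row.names = FALSE)
  }
  if (!is.null(report$distances)) {
    for (k in intersect(names(report$distances),
                        c("geographic", "climatic", "quantitative")))
      write_dist_matrix(report$distances[[k]], p(sprintf("dist_%s.csv", k)))
  }
  if (!is.null(report$inference$sequential))
    utils::write.csv(as.data.frame(report$inference$sequential),
                     p("sequential_regression.csv"), row.names = FALSE)
  if (!is.null(report$inference$qst_fst))
    utils::write.csv(report$inference$qst_fst, p("qst_fst.csv"),
                     row.names = FALSE)
  summary <- list(
    config = report$config[setdiff(names(report$config), "out_dir")],
    markers = report$markers[c("n_input", "n_kept", "n_loci")],
    error_rate = report$markers$error_rate$e,
    clone_threshold = report$markers$threshold,
    fst = report$popgen$fst$fst,
    fst_sd_loci = report$popgen$fst$sd_loci,
    fst_p = report$popgen$fst_test$p,
    amova_percent_among = unname(report$popgen$amova$percent[["among"]]),
    phi_st = report$popgen$amova$phi_st,
    mean_ppl = report$popgen$diversity$PPL[
      report$popgen$diversity$population == "mean"],
    mean_hen = report$popgen$diversity$H_eN[
      report$popgen$diversity$population == "mean"]
  )
  if (!is.null(report$inference)) {
    summary$ibd_molecular_r <- report$inference$ibd_molecular$r
    summary$ibd_molecular_p <- report$inference$ibd_molecular$p
    summary$ibd_quantitative_r <- report$inference$ibd_quantitative$r
    summary$ibd_quantitative_p <- report$inference$ibd_quantitative$p
    summary$distinctness_vs_diversity_r <-
      report$inference$distinctness_vs_diversity$r
  }
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(dir)
}

#' Reproduce the deposited-data analysis
#'
#' Runs the full molecular pipeline on a local copy of the study's archived
#' data deposit, exported to the package's plain CSV layout
#' (\code{markers.csv}, \code{traits.csv}, \code{sites.csv},
#' \code{climate.csv} in one directory).  The deposit itself is not shipped
#' with the package and must be downloaded separately.
#'
#' @param dir directory holding the exported deposit files.
#' @param ... configuration overrides passed to [run_all].
#' @return A \code{fragpop_report}.
#' @export
reproduce_deposit_analysis <- function(dir, ...) {
  if (!dir.exists(dir))
    stop("deposit directory not found: ", dir,
         "\nDownload the archived study data and export it to the plain ",
         "CSV layout described in ?reproduce_deposit_analysis.")
  paths <- list(markers = file.path(dir, "markers.csv"),
                traits = file.path(dir, "traits.csv"),
                sites = file.path(dir, "sites.csv"),
                climate = file.path(dir, "climate.csv"))
  missing <- !vapply(paths, file.exists, logical(1))
  if (any(missing))
    stop("deposit files missing: ",
         paste(unlist(paths)[missing], collapse = ", "))
  run_all(utils::modifyList(list(markers = paths$markers,
                                 traits = paths$traits,
                                 sites = paths$sites,
                                 climate = paths$climate),
                            list(...)))
}
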
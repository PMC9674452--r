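#!/usr/bin/env Rscript
# Stage 4: distance matrices and the drift-vs-selection inference layer.
# Geographic (haversine), climatic (PCA-reduced Euclidean) and quantitative
# (Mahalanobis on family means) distances; isolation-by-distance tests;
# sequential permutation regression of quantitative distance on molecular,
# climatic and geographic distances; distinctness vs diversity; Q_ST-F_ST.

suppressPackageStartupMessages(library(fragpop))

dat <- "results/data"
out <- "results/inference"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 17
n_perm <- 999

sites <- read.csv(file.path(dat, "sites.csv"))
climate <- read.csv(file.path(dat, "climate.csv"))
traits <- read.csv(file.path(dat, "traits.csv"))
pw_fst <- as.matrix(read.csv("results/popgen/pairwise_fst.csv",
                             row.names = 1, check.names = FALSE))
dist_tab <- read.csv("results/popgen/distinctness.csv")

d_geo <- geographic_distances(sites)
pca <- climate_pca(climate, k = 2)
cat(sprintf("Climate PCA: first two components explain %.1f%% (%.1f + %.1f)\n",
            sum(pca$explained[1:2]), pca$explained[1], pca$explained[2]))
d_clim <- climatic_distances(pca)
d_quant <- mahalanobis_distances(traits, c(diameter = "none",
                                           leaf_width = "none",
                                           flowers = "sqrt"))
write_dist_matrix(d_geo, file.path(out, "dist_geographic.csv"))
write_dist_matrix(d_clim, file.path(out, "dist_climatic.csv"))
write_dist_matrix(d_quant, file.path(out, "dist_quantitative.csv"))

pops <- rownames(pw_fst)
d_geo <- d_geo[pops, pops]; d_clim <- d_clim[pops, pops]
d_quant <- d_quant[pops, pops]

ibd_mol <- ibd_test(pw_fst, d_geo, n_perm, seed)
ibd_q <- ibd_test(d_quant, d_geo, n_perm, seed)
cat(sprintf("IBD, molecular vs geographic:    r = %.3f, p = %.3f\n",
            ibd_mol$r, ibd_mol$p))
cat(sprintf("IBD, quantitative vs geographic: r = %.3f, p = %.3f\n",
            ibd_q$r, ibd_q$p))

seq_res <- sequential_perm_regression(
  d_quant, list(molecular = pw_fst, climatic = d_clim, geographic = d_geo),
  n_perm, seed)
cat("Sequential permutation regression (quantitative distance):\n")
print(as.data.frame(seq_res), row.names = FALSE, digits = 3)
write.csv(as.data.frame(seq_res), file.path(out, "sequential.csv"),
          row.names = FALSE)

r_dd <- correlate(dist_tab$distinctness, dist_tab$H_eN)
cat(sprintf("Distinctness vs H_eN: r = %.2f (p = %.2g)\n", r_dd$r, r_dd$p))
sz <- sites$census_size[match(dist_tab$population, sites$population_id)]
r_sz <- correlate(dist_tab$H_eN, log10(sz))
cat(sprintf("H_eN vs log10 census size: r = %.2f (p = %.2g)\n",
            r_sz$r, r_sz$p))

# Q_ST vs F_ST verdicts
qs_global <- read.csv("results/quantgen/global.csv")
m_clean <- {
  m <- read_marker_matrix(file.path(dat, "markers.csv"), "csv")
  repl_df <- read.csv(file.path(dat, "replicates.csv"))
  repl <- lapply(split(repl_df, repl_df$pair),
                 function(d) list(d$original, d$replicate))
  thr <- clone_threshold(estimate_error_rate(repl), ncol(m$scores))
  deduplicate(m, detect_clones(m, thr$threshold), seed)
}
fst_t <- fst_permutation_test(m_clean, 0.643, n_perm, seed)
qf <- compare_qst_fst(qs_global, fst_t)
print(qf, row.names = FALSE, digits = 3)
write.csv(qf, file.path(out, "qst_fst.csv"), row.names = FALSE)
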